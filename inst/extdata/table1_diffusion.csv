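species,concentration_g_per_L,D_obs_1e11_m2s,D_mic_1e11_m2s
p-cresol,1.56,79,NA
p-cresol,3.12,76,7.8
p-cresol,6.25,69,7.5
p-cresol,12.5,58,7.0
p-cresol,25,44,6.3
p-cresol,50,29,5.3
p-cresol,100,17,4.0
p-cresol,200,7.0,2.0
guaiacol,1.56,78,6.6
guaiacol,3.12,76,7.4
guaiacol,6.25,72,7.8
guaiacol,12.5,68,7.6
guaiacol,25,60,7.3
guaiacol,50,47,6.4
guaiacol,100,31,4.8
guaiacol,200,16,2.3
phenol,1.56,91,7.2
phenol,3.12,87,8.4
phenol,6.25,83,8.1
phenol,12.5,76,7.6
phenol,25,66,7.7
phenol,50,53,6.1
phenol,100,35,4.4
phenol,200,17,2.1
pyrocatechol,1.56,80,6.5
pyrocatechol,3.12,79,7.5
pyrocatechol,6.25,75,7.6
pyrocatechol,12.5,72,7.8
pyrocatechol,25,65,7.2
pyrocatechol,50,54,6.5
pyrocatechol,100,39,5.1
pyrocatechol,200,20,2.6
resorcinol,1.56,78,NA
resorcinol,3.12,78,NA
resorcinol,6.25,75,8.0
resorcinol,12.5,71,7.7
resorcinol,25,65,7.3
resorcinol,50,56,6.5
resorcinol,100,44,5.1
resorcinol,200,26,2.6
hydroquinone,1.56,81,NA
hydroquinone,3.12,80,7.8
hydroquinone,6.25,78,8.0
hydroquinone,12.5,74,8.1
hydroquinone,25,73,7.5
hydroquinone,50,64,6.8
hydroquinone,100,50,5.4
hydroquinone,200,33,2.9
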