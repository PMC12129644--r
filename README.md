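# soludiff

Quantifying micellar solubilization from pulsed-field-gradient (PFG) NMR
diffusion decays.

Surfactant micelles dissolve poorly water-soluble organics — the basis of
micellar extraction and remediation technologies. PFG-NMR diffusometry
measures, species-selectively, how fast every component of such a solution
diffuses; because a solubilizate molecule exchanges rapidly between the
aqueous phase and the (much slower) micelles, its observed self-diffusion
coefficient is the population-weighted average

D<sub>obs</sub> = p·D<sub>mic</sub> + (1 − p)·D<sub>free</sub>,

so the micelle-bound fraction follows as
p = (D<sub>free</sub> − D<sub>obs</sub>)/(D<sub>free</sub> − D<sub>mic</sub>),
and from it the micelle–water partition coefficient K<sub>m</sub> = p/(1 − p)
and the molar solubilization ratio
MSR = p·(C<sub>sol</sub>/M<sub>sol</sub>) / ((C<sub>surf</sub> − CMC)/M<sub>surf</sub>).

`soludiff` implements this pipeline end to end for rhamnolipid/phenol
systems (and analogous surfactant/solubilizate series):

* the stimulated-echo attenuation model (`b_factor()`, `echo_amplitude()`,
  rectangular and sine gradient shapes);
* mono- and bi-exponential decay fitting with the initial/tail window
  strategies used for surfactant methylene signals (`fit_monoexp()`,
  `fit_biexp()`, `choose_window()`, `assign_micelle_component()`);
* the two-state fast-exchange analysis (`bound_fraction()`,
  `partition_coefficient()`, `molar_solubilization_ratio()`,
  `analyze_series()`);
* CMC estimation from the diffusion–concentration breakpoint
  (`estimate_cmc()`);
* a seeded synthetic decay generator for validation without spectrometer
  data (`default_scenario()`, `write_fixture()`).

A packaged diffusion-coefficient table for six phenols (phenol, p-cresol,
guaiacol, pyrocatechol, resorcinol, hydroquinone) across rhamnolipid
concentrations of 1.56–200 g/L ships in `inst/extdata/` and drives the
worked example below.

## Worked example

```r
library(soludiff)
tab <- run_table1()   # packaged six-phenol series, default config
tab[tab$C_RL_g_per_L %in% c(50, 200) & tab$solute %in% c("p-cresol", "hydroquinone"), ]
```

```
       solute C_RL_g_per_L D_S_1e11 D_mic_1e11 p_percent Km_percent MSR_x100
     p-cresol           50       29        5.3        68        211       41
     p-cresol          200        7        2.0        94       1440       14
 hydroquinone           50       64        6.8        23         30       14
 hydroquinone          200       33        2.9        61        159        9
```

Reading the p-cresol row at 200 g/L: the observed p-cresol diffusion
coefficient (7.0×10⁻¹¹ m²/s) has fallen almost to the micelle value
(2.0×10⁻¹¹ m²/s), so 94 % of the p-cresol is micelle-bound
(p = (79 − 7)/(79 − 2)); the partition coefficient p/(1 − p) is ≈ 14.4
(1440 %), and each mole of micellized rhamnolipid carries ≈ 0.14 mol of
p-cresol (MSR×100 = 14). The mono-hydroxyl phenols bind more strongly than
the di-hydroxyl ones (hydroquinone: 61 % bound, MSR×100 = 9) — a second
hydroxyl group raises hydrophilicity and keeps more of the solute in the
aqueous phase. Bound fractions at the lowest concentrations are sensitive
to the free-solution diffusion coefficient, which defaults to the
lowest-concentration observed value and can be overridden via
`series_config(d_free = ...)`.

The same analysis runs from raw decay curves: `read_decay_csv()` →
`fit_monoexp()`/`fit_biexp()` → `fit_decay_table()` → `analyze_series()`.
A thin command-line wrapper with `simulate`, `fit`, `solubilize`, `cmc`
and `table1` modes is installed at `inst/cli/soludiff.R`.

See the vignette
(`vignettes/micellar-solubilization-diffusometry.Rmd`) for the models,
fitting strategies, the synthetic-data generator and known limitations.

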