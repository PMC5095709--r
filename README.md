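# difcanal

Quantification of conventional aqueous-outflow changes from **differential
two-dye canalograms** of enucleated eyes, with a synthetic eye-phantom
generator for fully reproducible testing.

## The problem and who this is for

Canalograms visualize the perilimbal outflow channels of an (ex vivo) eye by
perfusing a fluorescent tracer into the anterior chamber: quadrants with
more conventional outflow fill earlier and brighter. Researchers evaluating
microincisional glaucoma surgeries — trabecular micro-bypass stents (TMB)
and ab interno trabeculectomy (AIT) — need to compare the *same eye* before
and after surgery. One dye cannot do this (incomplete washout contaminates
the second run), so the differential method perfuses fluorescein (FU) before
surgery and Texas red (TR) after, and reconciles the dyes with a measured
normalization coefficient.

## The method in brief

For each eye, with quadrants q ∈ {IN, SN, ST, IT}:

* **Read-out frame**: the frame whose pooled perilimbal FU intensity best
  matches half the lapse maximum; the same frame number is read in the TR
  lapse.
* **Normalization**: from control eyes (no surgery between dyes),
  c = mean over eyes of the quadrant-averaged FU/TR ratio at that frame
  (≈ 1.56 under the default phantom physics).
* **Percent change**: Δ_q = 100 · (c·TR_q − FU_q) / FU_q.
* **Flow rates**: the 3 µL/min total aqueous inflow of the porcine eye is
  partitioned across quadrants in proportion to control fluorescence
  (φ_q sums to the total exactly), and post-surgical flow is
  φ_q · (1 + Δ_q/100).
* **Inference**: per-quadrant matched-pair t-tests across eyes, unpaired
  t-tests for laterality checks, and exact noncentral-t sample-size
  calculation.

Dye optics follow a self-quenching emission model
F(C) = b·t_exp·C·exp(−C/C_q) (linear at low concentration, unimodal with a
peak at the quench scale), and `quench_scan()` verifies that working
concentrations sit below the quench regime.

Because no public canalogram data exist, the `simulate_*` functions generate
paired FU/TR time lapses (multi-page 16-bit TIFF with 14-bit payload, JSON
metadata sidecars) with known per-quadrant ground-truth flow, per-eye
biological jitter, and camera noise. See the methods vignette
(`vignettes/differential-canalograms.Rmd`) for the model, parameter
defaults, and known limitations.

## Worked example

```r
library(difcanal)

# eight simulated control eyes under the default configuration
pairs <- simulate_control_pairs(n_eyes = 8, seed = 1)
cal <- estimate_normalization(pairs)
glance(cal)
#> # A tibble: 1 × 3
#>       c n_eyes method
#>   <dbl>  <int> <chr>
#> 1  1.54      8 per_eye

# one eye after (simulated) ab interno trabeculectomy
eye <- simulate_eye(99, effect = surgery_effect("AIT"))
res <- run_differential(eye$fu, eye$tr, eye$geom, cal)
res
#> <canalogram_result> frame 25, c = 1.539, total inflow 3.0 uL/min
#> # A tibble: 4 × 6
#>   quadrant    fu tr_corrected percent_change flow_before flow_after
#>   <fct>    <dbl>        <dbl>          <dbl>       <dbl>      <dbl>
#> 1 IN       5678.       10517.             85        0.82       1.51
#> 2 SN       6072.        9817.             62        0.87       1.41
#> 3 ST       4138.        4844.             17        0.59       0.7
#> 4 IT       4984.        6641.             33        0.72       0.95
```

Reading the output: the calibration run recovers the TR→FU coefficient from
the control cohort. The AIT eye then shows the expected
circumferential-nasal pattern — large inferonasal/superonasal enhancement
(+85%, +62% against generator truth +100%, +75%), mild superotemporal
change — and the baseline flows (0.82, 0.87, 0.59, 0.72 µL/min) sum to the
3 µL/min inflow by construction. `autoplot(res)` draws the per-quadrant bar
chart; `summarize_group()` aggregates many eyes with SEM and paired
t-tests.

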