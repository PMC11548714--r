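# pfmqa — quality assessment of pelvic floor muscle contractions

Pelvic floor muscle (PFM) training is the first-line treatment for urinary
incontinence, but it only works when contractions are performed correctly.
Clinicians grade contraction strength by digital palpation on the Modified
Oxford Scale (MOS, 0 = nil … 5 = strong), a subjective exam; intra-vaginal
dynamometry instead records the contraction objectively as a force–time
trace in newtons. `pfmqa` turns such traces into automated feedback for
physiotherapists, researchers and device developers:

* **Contraction detection.** A small 1D convolutional network
  (conv(32, 3) → batch norm → ReLU, twice, → global average pooling →
  softmax; 3426 parameters) classifies a trace as *PFM contraction* vs
  *non-contraction* (rest, cough, push), trained with Adam, batch size 32,
  up to 100 epochs with early stopping and learning-rate reduction on
  plateau, and evaluated by stratified five-fold cross-validation
  (accuracy, sensitivity, specificity, ROC/AUC).
* **Contraction quality.** The 10 s maximal voluntary contraction (MVC) is
  fitted by a five-segment piecewise-linear *trapezoid model*
  F(t) = {mᵢt+bᵢ, m_r t+b_r, m_c t+b_c, m_f t+b_f} over the corner points
  A ≤ B < C ≤ D < E, located on the smoothed first derivative by a
  descending threshold ladder (onset B, end E) and zero crossings (plateau
  C, D). Seven clinical features follow: rising slope m_r, falling slope
  m_f, area under the contraction AUC_c, peak force ΔF_max, average force
  F̄_c, contraction time T_c, and muscle relaxation ΔF_f−i, combined into an
  overall rating (c₁ΔF̂max + c₂T̂c + c₃F̄̂c + c₄(m̂r+m̂f)/2 + c₅ΔF̂f−i)×100
  on normalized features.
* **Strength grading.** Random forest (plain and importance-pruned),
  gradient boosting and multinomial logistic regression map normalized
  features to MOS grades, scored with the clinically motivated ±1-class
  margin.
* **Legacy data.** 1024 Hz recordings are decimated to 20 Hz via a
  zero-phase fourth-order Butterworth low-pass at the new Nyquist frequency,
  with reconstruction fidelity quantified by RMSPE and dominant-frequency
  comparison.
* **Synthetic data.** Clinical dynamometry datasets are private, so a seeded
  generator emulates all four tasks (trapezoidal MVCs whose amplitude scales
  with grade, flat rests, cough spike trains, slow push drifts) with
  analytic ground truth for every MVC.

See the methods vignette (`vignettes/pfmqa-methods.Rmd`) for the model
details, parameter rationale, and what the synthetic benchmarks do and do
not demonstrate.

## Worked example

```r
library(pfmqa)

# a synthetic grade-4 MVC with ground truth
it <- gen_mvc(grade = 4, generator_params(), seed = 42)
it$recording
#> <pfm_recording> task=mvc  200 samples @ 20 Hz (10.00 s)  subject=anon session=s1
#>   MOS grade: 4

fx <- extract_features(it$recording)
fx
#> <contraction features> rise 35.967 N/s  fall -18.157 N/s  AUC 149.63 N.s
#>   Fmax 25.78 N  Favg 22.02 N  Tc 6.75 s  relaxation 4.148 N
```

The extracted rising/falling slopes (35.97, −18.16 N/s) sit within 1–2% of
the generator's ground truth for this trace (36.41, −18.24 N/s): the fit
recovered the contraction geometry despite 2% sensor noise. `Fmax` is the
peak force, `Tc` the contraction duration between onset and release, and
`relaxation` the 4.1 N of residual force the simulated subject failed to
release afterwards. Normalizing features across a table of recordings and
applying equal weights gives the overall rating — the stronger, longer
contraction rates higher:

```r
it2 <- gen_mvc(grade = 2, generator_params(), seed = 43)
df <- features_to_df(list(fx, extract_features(it2$recording)))
nt <- normalize_features(df)$table
overall_rating(nt[1, ])  #> 60   (grade-4 contraction)
overall_rating(nt[2, ])  #> 40   (grade-2 contraction)
```

A command-line interface wraps the same functions
(`synth`, `downsample`, `extract`, `rate`, `validate-extraction`,
`detect-train`, `detect-eval`, `detect-cv`, `strength-train`,
`strength-eval`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pfmqa.R", package = "pfmqa"))')
Rscript "$CLI" synth --out data/ --seed 7 --mvc 50 --rest 50
Rscript "$CLI" extract --manifest data/manifest.json --out features.csv
```

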