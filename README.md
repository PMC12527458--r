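# mcactivity

Disease-activity scoring and validation for microscopic colitis (MC).

Microscopic colitis — collagenous and lymphocytic colitis — causes chronic
watery diarrhea, urgency, fecal leakage and nocturnal stools despite a
macroscopically normal colon. Clinical practice grades activity with the
binary Hjortswang criteria (mean ≥ 3 stools/day or ≥ 1 watery, Bristol
type 7, stool/day over a diary week), which cannot distinguish mild from
severe disease. `mcactivity` implements a complete, tested pipeline for a
graded patient-reported severity index on top of a 7-day symptom diary, for
biostatisticians and trialists who need a reproducible implementation of
every step:

* **Diary scoring** — weekly aggregation of daily stool counts (total,
  nocturnal, Bristol 6/7, solid), urgency, leakage and abdominal pain;
  Hjortswang activity classification.
* **Microscopic Colitis Score (MCS)** — a composite 0–15 score: each of
  five items (mean loose stools/day, mean nocturnal stools/day,
  urgency days/week, leakage days/week, mean pain) earns 0–3 points through
  an item → points threshold table, and the points are summed:

  MCS = Σᵢ pointsᵢ(xᵢ),  MCS ∈ {0, …, 15},

  with severity groups remission (0–3), mild (4–6), moderate (7–9) and
  severe (10–15). Mean solid stools and mean total stools are excluded:
  total = loose + solid by construction, and neither adds predictive value.
* **Anchor calibration** — item cut-offs are derived from data so that each
  awarded point corresponds to a 15–20 point decrease in the IBDQ-32 total
  (32–224, higher = better quality of life), the instrument's established
  clinically-significant difference; includes the diarrhea-item model
  comparison (loose vs Bristol 6 vs Bristol 7 stools by adjusted R²).
* **Psychometric validation** — Bartlett sphericity, KMO sampling adequacy,
  parallel analysis, exploratory factor analysis (least-squares extraction,
  promax rotation), Cronbach's alpha, ICC(2,k) test–retest reliability with
  exact F-based confidence intervals, paired Wilcoxon responsiveness with
  Bonferroni correction, and convergent-validity correlation hypotheses.
* **Unsupervised severity groups** — missingness filtering (> 20% rows then
  columns), iterative random-forest imputation, scaling + PCA with JackStraw
  dimension significance, shared-nearest-neighbour Jaccard graph (k = 10)
  and Leiden partitioning (resolution 0.9), with burden-ordered severity
  annotation.
* **ROC cut-off selection** — tie-aware AUC (equal to the Mann–Whitney
  concordance), Youden-J optimal cut-offs, and the standard severity
  contrasts (Hjortswang-active; cluster-derived any-active, ≥ moderate,
  severe).
* **Synthetic cohort generator** — patient-level data of the validation
  study are not public, so the package ships a two-timepoint cohort
  generator (default n = 131, ≈ 1:1 remission:active) in which a latent
  severity stratum drives the diary and quality of life follows
  IBDQ-32 = 202.3 − 6.0 · MCS + N(0, 20²); every pipeline stage is
  exercised and tested end-to-end against this generator's known truth.

## Worked example

```r
library(mcactivity)

# simulate a cohort at the study design, score it, validate, cluster
report <- run_pipeline(run_config(seed = 4))

# one patient's week: 2 watery + 1 solid stool per day, urgency on 3 days
days <- data.frame(day_index = 1:7, total = 3, nocturnal = 1, bristol6 = 0,
                   bristol7 = 2, solid = 1,
                   urgency = c(1, 1, 0, 0, 1, 0, 0), leakage = 0, pain = 1)
s <- summarize_diary(days)
hjortswang_classify(s)
#> $active    [1] TRUE      (mean_total = 3 >= 3 and mean_b7 = 2 >= 1)
#> $rule_fired [1] "both"
compute_mcs(s)
#> $item_points  mean_loose mean_nocturnal urgency_days leakage_days mean_pain
#>                        1              1            1            0         1
#> $mcs      [1] 4
#> $severity [1] "mild"
```

The diary averages 2 loose (watery) stools/day (1 point, interval [1, 3)),
1 nocturnal stool/day (1 point), urgency on 3 days/week (1 point), no
leakage (0 points) and constant mild pain (1 point): MCS 4, mild disease,
active by both Hjortswang clauses.

On the simulated cohort above, `report$validate` carries the psychometric
battery (e.g. Cronbach's alpha 0.93 over the five scored items, all
convergent-validity hypotheses met with MCS vs IBDQ-32 total
r ≈ −0.73), and `report$roc` the severity contrasts (all AUCs > 0.95 at
the generator's default separation).

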