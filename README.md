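# cecleanr

Objective cleanliness scoring of capsule-endoscopy (CE) frames in R.

Small-bowel capsule endoscopy records hours of video whose diagnostic value
depends on how much of the mucosa is visible: bile, bubbles and food debris
("intestinal content") can occlude it. Studies comparing patient-preparation
protocols have been inconclusive largely because cleanliness was judged by
eye, and human ratings are noisy — experts disagree with each other and even
with their own earlier ratings. `cecleanr` implements a fully automatic,
deterministic alternative for researchers who need a reproducible cleanliness
measure: the same frame always receives the same score, so the method's
intrarater reliability is exactly 1.

## The method

1. **Patch classification.** The circular field of view (FOV) of a
   576×576 frame is detected and divided into overlapping 64×64 patches on a
   32-pixel lattice. A light-weight CNN trained from scratch classifies each
   patch as clean mucosa or intestinal content. The network has 4 blocks of
   3×3 convolutions with Leaky ReLU activations and batch normalisation;
   each block ends in a stride-2 convolution (no pooling), and a
   flatten → dense(128) → softmax(2) head completes the model — 1,708,610
   parameters in total, against 14,977,730 for a VGG-16 with the same head.
2. **Pixel probabilities.** Patch probabilities are planted at the patch
   centres and bilinearly interpolated to every FOV pixel (overlapping
   patches make the lattice dense enough for a smooth probability map, which
   can be rendered as a heat map over the frame).
3. **Cleanliness score.** The mean dirty probability p̄ over the FOV is
   mapped to the 4-category ordinal scale — Poor (1), Fair (2), Good (3),
   Excellent (4) — through three thresholds t₁ < t₂ < t₃:
   p̄ < t₁ → Excellent, … , p̄ ≥ t₃ → Poor.
4. **Threshold learning.** The thresholds are not fixed a priori: they are
   learned by exhaustive grid search maximising the single-rater consistency
   intraclass correlation ICC(C,1) between the method's scores and two
   experts' scores, under video-grouped 5-fold cross-validation so the
   thresholds applied to a frame never saw that frame's video.
5. **Validation statistics.** Agreement is quantified with linearly weighted
   Cohen's kappa, κ₁ (weights w_ij = 1 − |i−j|/3, CI via the
   Fleiss–Cohen–Everitt large-sample standard error) and with single-rater
   ICC in consistency ICC(C,1) and absolute-agreement ICC(A,1) forms
   (two-way model, McGraw–Wong F-based confidence intervals).

A seeded synthetic-frame generator (circular FOV, textured mucosa, bile-like
blobs, bubble clusters, debris speckle, exact ground-truth masks) makes the
entire pipeline testable without clinical data.

## Worked example

```r
library(cecleanr)

count_parameters(build_proposed_cnn())
#> [1] 1708610

# train a reduced-width model on synthetic patches
d  <- generate_labeled_patches(600, seed = 42)
sp <- train_val_split(seq_len(dim(d$x)[4]), 0.8, seed = 1)
fit <- train_model(build_proposed_cnn(0.25),
                   d$x[, , , sp$train], d$labels[sp$train],
                   d$x[, , , sp$val],  d$labels[sp$val],
                   hyper_params(max_epochs = 5, seed = 1))
evaluate_model(fit$model, d$x[, , , sp$val], d$labels[sp$val])
#> accuracy 100.00%  sensitivity 100.00%  specificity 100.00%  MCC 1.0000

# score a frame whose true content coverage is 0.55
g <- generate_frame(synthetic_frame_params(dirty_fraction = 0.55, seed = 7))
score_frame(g$frame, fit$model, threshold_triple(0.42, 0.66, 0.94),
            mask = g$mask)
#> frame synthetic (video v1): Good (mean dirty probability 0.539)
```

The estimated mean dirty probability (0.539) tracks the generator's true
coverage (0.55), and the published thresholds place the frame in "Good".
Threshold learning and the agreement statistics on a synthetic rating study
(200 frames, two experts with 10% adjacent-category noise, true thresholds
0.42/0.66/0.94):

```r
rs <- generate_rating_study(20, 10, threshold_triple(0.42, 0.66, 0.94),
                            flip_prob = 0.1, seed = 3)
cv <- cross_validated_scores(rs$mean_probs, rs$ratings, rs$video_ids,
                             grouped_kfold(rs$video_ids, 5, seed = 1))
cv$summary
#>  threshold       boundary  mean          sd
#>         t1 Excellent/Good 0.420 0.000000000
#>         t2      Good/Fair 0.658 0.004472136
#>         t3      Fair/Poor 0.928 0.004472136

linear_weighted_kappa(cv$scores$method_code, rs$ratings[, 1])
#> weighted kappa 0.873 (95% CI 0.824, 0.922), n = 200

icc_single(rating_table(cbind(method = cv$scores$method_code,
                              unclass(rs$ratings))), "A1")
#> ICC(A,1) = 0.900 (95% CI 0.875, 0.921), n = 200 frames, 3 raters
```

The learned cut-points recover the generating thresholds to within one or
two grid steps with per-fold standard deviations under 0.005.

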