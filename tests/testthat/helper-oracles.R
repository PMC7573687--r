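# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: the bilinear oracle evaluates the textbook
# formula pixel by pixel, the metric oracle recounts the confusion matrix,
# and the Python oracle calls statsmodels / pingouin.

# brute-force per-pixel bilinear interpolation over planted patch centres,
# with the same clamp-to-nearest-centre rule at the borders
brute_force_bilinear <- function(grid, probs, mask) {
  half <- grid$patch_size %/% 2L
  centers_r <- sort(unique(grid$anchors[, 1L] + half))
  centers_c <- sort(unique(grid$anchors[, 2L] + half))
  V <- matrix(NA_real_, length(centers_r), length(centers_c))
  for (i in seq_len(nrow(grid$anchors))) {
    V[match(grid$anchors[i, 1L] + half, centers_r),
      match(grid$anchors[i, 2L] + half, centers_c)] <- probs[i]
  }
  stopifnot(!anyNA(V)) # oracle is for full lattices only
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (!mask[r, c]) next
      y <- r - 1; x <- c - 1
      i0 <- max(which(centers_r <= y), 1L)
      if (length(which(centers_r <= y)) == 0L) i0 <- 1L
      i1 <- min(i0 + 1L, length(centers_r))
      j0 <- max(which(centers_c <= x), 1L)
      if (length(which(centers_c <= x)) == 0L) j0 <- 1L
      j1 <- min(j0 + 1L, length(centers_c))
      ty <- if (i1 > i0) (y - centers_r[i0]) / (centers_r[i1] - centers_r[i0]) else 0
      tx <- if (j1 > j0) (x - centers_c[j0]) / (centers_c[j1] - centers_c[j0]) else 0
      ty <- min(max(ty, 0), 1); tx <- min(max(tx, 0), 1)
      out[r, c] <- (1 - ty) * (1 - tx) * V[i0, j0] + (1 - ty) * tx * V[i0, j1] +
        ty * (1 - tx) * V[i1, j0] + ty * tx * V[i1, j1]
    }
  }
  out
}

# recount a confusion matrix from labels and hard predictions
brute_force_metrics <- function(truth, pred) {
  tp <- sum(truth == 2 & pred == 2); tn <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 1 & pred == 2); fn <- sum(truth == 2 & pred == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = 100 * (tp + tn) / length(truth),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# run statsmodels (weighted kappa + SE) and pingouin (ICC) on rating tables;
# returns a data.frame aligned with the input list
python_agreement_oracle <- function(tables) {
  dir <- tempfile("xcheck")
  dir.create(dir)
  for (i in seq_along(tables))
    utils::write.csv(as.data.frame(tables[[i]]),
                     file.path(dir, sprintf("t%03d.csv", i)), row.names = FALSE)
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import glob, json, sys",
    "import numpy as np, pandas as pd",
    "from statsmodels.stats.inter_rater import cohens_kappa",
    "import pingouin as pg",
    sprintf("files = sorted(glob.glob('%s/t*.csv'))", dir),
    "rows = []",
    "for f in files:",
    "    tb = pd.read_csv(f)",
    "    ct = np.zeros((4, 4))",
    "    for x, y in zip(tb.iloc[:, 0], tb.iloc[:, 1]):",
    "        ct[int(x) - 1, int(y) - 1] += 1",
    "    k = cohens_kappa(ct, wt='linear')",
    "    long = tb.reset_index().melt(id_vars='index', var_name='r', value_name='s')",
    "    icc = pg.intraclass_corr(long, 'index', 'r', 's')",
    "    c1 = icc[icc.Type == 'ICC(C,1)'].iloc[0]",
    "    a1 = icc[icc.Type == 'ICC(A,1)'].iloc[0]",
    "    rows.append(dict(kappa=float(k.kappa), se=float(np.sqrt(k.var_kappa)),",
    "                     c1=float(c1.ICC), a1=float(a1.ICC)))",
    sprintf("json.dump(rows, open('%s/out.json', 'w'))", dir)),
    script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  out_file <- file.path(dir, "out.json")
  if (!file.exists(out_file))
    stop("python oracle failed: ", paste(status, collapse = "\n"))
  do.call(rbind, lapply(jsonlite::read_json(out_file, simplifyVector = FALSE),
                        as.data.frame))
}

# small deterministic frame for geometry tests
tiny_gray_frame <- function(n = 576L, value = 128L) {
  ce_frame(array(value, c(n, n, 3L)), "gray", "v0")
}
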