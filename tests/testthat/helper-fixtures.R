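# Shared fixtures: record/cohort builders and brute-force oracles.

make_record <- function(...) {
  rec <- list(subject_id = "S0001", age = 52, stature_m = 1.57,
              body_mass_kg = 107.8, wc_cm = 121, hc_cm = 133,
              fm_kg = NA_real_, fm_fraction = 0.509, sbp = 127,
              dbp = 77, glucose_mgdl = 97, tg_mgdl = 131.6,
              hdl_mgdl = 50.1, on_glucose_drug = FALSE,
              on_bp_drug = FALSE, on_tg_drug = FALSE,
              on_hdl_drug = FALSE)
  utils::modifyList(rec, list(...))
}

# random valid cohort of n subjects (plain independent draws; the
# copula generator has its own tests)
random_cohort <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("R%04d", seq_len(n)),
    age = runif(n, 20, 80),
    stature_m = runif(n, 1.45, 1.80),
    body_mass_kg = runif(n, 70, 160),
    wc_cm = runif(n, 85, 150),
    hc_cm = runif(n, 95, 170),
    fm_kg = NA_real_,
    sbp = runif(n, 100, 170),
    dbp = runif(n, 60, 100),
    glucose_mgdl = runif(n, 70, 160),
    tg_mgdl = runif(n, 50, 350),
    hdl_mgdl = runif(n, 25, 90),
    on_glucose_drug = runif(n) < 0.1,
    on_bp_drug = runif(n) < 0.2,
    on_tg_drug = runif(n) < 0.05,
    on_hdl_drug = runif(n) < 0.02,
    stringsAsFactors = FALSE
  ) |>
    (\(d) { d$fm_kg <- runif(n, 0.35, 0.60) * d$body_mass_kg; d })()
}

# O(m * n) pairwise Mann-Whitney AUC, the independent oracle
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exhaustive Youden scan over every distinct score and -Inf,
# positivity = score > cutoff, smallest maximising cutoff
brute_youden <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cand <- c(-Inf, sort(unique(scores)))
  best_j <- -Inf
  best_c <- NA_real_
  for (ct in cand) {
    j <- mean(pos > ct) + mean(neg <= ct) - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- ct
    }
  }
  list(cutoff = best_c, youden = best_j)
}
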