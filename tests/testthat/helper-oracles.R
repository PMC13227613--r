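# Independent oracles used to pin the fast implementations.

# literal application of the epoch rule: derive the six leaf durations,
# find those strictly exceeding the cutoff, refine stepping by cadence
epoch_oracle <- function(row, theta_LM = 90, theta_MV = 130, cutoff = 30) {
  lying <- row[["lying_primary_s"]] + row[["lying_secondary_s"]]
  sitnt <- max(row[["sedentary_s"]] - row[["sitting_transport_s"]], 0)
  stand <- max(row[["upright_s"]] - row[["stepping_s"]] - row[["cycling_s"]], 0)
  durs <- c(Lying = lying, SittingNotInTransport = sitnt,
            SittingInTransport = row[["sitting_transport_s"]],
            Standing = stand, Stepping = row[["stepping_s"]],
            Cycling = row[["cycling_s"]])
  over <- names(durs)[durs > cutoff]
  if (length(over) != 1L) return(excluded_label())
  if (over == "Stepping") {
    s <- row[["steps"]]
    if (!is.na(theta_MV) && s >= theta_MV) return("VigorousStepping")
    if (s >= theta_LM) return("ModerateStepping")
    return("LowStepping")
  }
  over
}

# random epoch compositions honouring the export invariants
random_epochs <- function(n, seed = 1) {
  set.seed(seed)
  leaf <- c("lying", "sitnt", "sitt", "stand", "step", "cyc")
  rows <- lapply(seq_len(n), function(k) {
    m <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
    picks <- sample(leaf, m)
    total <- sample(c(60, sample(30:60, 1)), 1, prob = c(0.8, 0.2))
    secs <- if (m == 1) total else {
      cuts <- sort(sample(seq_len(total - 1), m - 1))
      diff(c(0, cuts, total))
    }
    v <- stats::setNames(rep(0, 6), leaf)
    v[picks] <- secs
    lp <- round(v[["lying"]] * runif(1))
    data.table::data.table(
      participant_id = "PX",
      minute_start = as.POSIXct("2026-01-05", tz = "UTC") + 60 * k,
      sedentary_s = v[["sitnt"]] + v[["sitt"]],
      sitting_transport_s = v[["sitt"]],
      lying_primary_s = lp, lying_secondary_s = v[["lying"]] - lp,
      upright_s = v[["stand"]] + v[["step"]] + v[["cyc"]],
      stepping_s = v[["step"]], cycling_s = v[["cyc"]],
      steps = if (v[["step"]] > 0) sample(40:170, 1) else 0,
      met = NA_real_)
  })
  data.table::rbindlist(rows)
}

# O(n^2) pairwise Mann-Whitney AUC
auc_oracle <- function(confidence, truth) {
  pos <- confidence[truth == 1]
  neg <- confidence[truth == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# exhaustive grid maximization of J over all candidate thresholds
youden_oracle <- function(confidence, truth) {
  cands <- c(Inf, sort(unique(confidence), decreasing = TRUE))
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  best_j <- -Inf; best_t <- Inf
  for (t in cands) {
    pred <- confidence >= t
    j <- sum(pred & truth == 1) / n_pos - sum(pred & truth == 0) / n_neg
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(threshold = best_t, J = best_j)
}

# per-cell binomial check of empirical proportions against expected ones
within_multinomial_ci <- function(counts, probs, z = 3.5) {
  n <- sum(counts)
  phat <- counts / n
  all(abs(phat - probs) <= z * sqrt(probs * (1 - probs) / n) + 1e-12)
}
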