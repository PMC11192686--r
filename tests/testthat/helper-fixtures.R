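options(itasense.verbose = FALSE)

# two participants, perfectly separated RTs: median split classifies all
# trials correctly (log-linear rates 0.9 / 0.1 per participant)
toy_search <- function() {
  one <- data.frame(
    epoch = 1L, block = 1L,
    condition = rep(c("repeated", "new"), each = 4),
    rt_ms = c(300, 310, 320, 330, 400, 410, 420, 430))
  trial_table(rbind(cbind(participant = "a", one),
                    cbind(participant = "b", one)), "search")
}

toy_recognition <- function(n_per_cond = 12, p_correct = 1) {
  resp <- function(cond) {
    hit <- stats::runif(n_per_cond) < p_correct
    ifelse(cond == "repeated", ifelse(hit, "old", "new"),
           ifelse(hit, "new", "old"))
  }
  rows <- do.call(rbind, lapply(c("a", "b"), function(p) {
    data.frame(participant = p,
               condition = rep(c("repeated", "new"), each = n_per_cond),
               response = c(resp(rep("repeated", n_per_cond)),
                            resp(rep("new", n_per_cond))))
  }))
  trial_table(rows, "recognition")
}

# gaussian search table with known per-participant separation delta (latent
# d-prime = delta / sigma), one epoch
latent_search <- function(n_participants, k_per_cond, dprime, sigma = 1,
                          baseline = 100 * sigma) {
  rows <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    data.frame(
      participant = sprintf("P%02d", i), epoch = 1L, block = 1L,
      condition = rep(c("repeated", "new"), each = k_per_cond),
      rt_ms = baseline + c(rnorm(k_per_cond, -dprime * sigma / 2, sigma),
                           rnorm(k_per_cond, dprime * sigma / 2, sigma)))
  }))
  trial_table(rows, "search")
}
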