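# fixtures are built in code; no data files

# an all-negative subject profile; override any field via ...
make_profile <- function(...) {
  p <- data.frame(
    subject_id = "s1", age = 70L, sex = "female", height = 160, weight = 56.3,
    bmi = 22.0, lives_alone = FALSE, marital_status = "married",
    noise_history = FALSE, family_deafness = FALSE, diet = "light",
    exercise_habit = TRUE, smoking = FALSE, drinking = FALSE,
    headset_habit = FALSE, hypertension = FALSE, diabetes = FALSE,
    hyperlipidemia = FALSE, cardio_cerebrovascular = FALSE,
    hyperuricemia = FALSE, hypothyroidism = FALSE,
    ototoxic_drug_history = FALSE)
  over <- list(...)
  p[names(over)] <- over
  p
}

# full screening record for one subject: profile + HHIE + tones (+ PTA)
make_subject <- function(..., hhie = rep("never", 10),
                         heard = c(2L, 2L, 2L, 2L), pta = rep(20, 8)) {
  p <- make_profile(...)
  h <- as.data.frame(as.list(hhie))
  names(h) <- hhie_columns()
  tones <- data.frame(heard_2k_left = heard[1],
                      heard_500_left = if (heard[1] == 2L) heard[2] else NA_integer_,
                      heard_2k_right = heard[3],
                      heard_500_right = if (heard[3] == 2L) heard[4] else NA_integer_)
  thr <- as.data.frame(as.list(pta))
  names(thr) <- pta_columns()
  cbind(p, h, tones, thr)
}

random_confusion <- function() {
  repeat {
    k <- as.integer(rmultinom(1, sample(1:200, 1), rep(0.25, 4)))
    if (sum(k) > 0) return(confusion_matrix(k[1], k[2], k[3], k[4]))
  }
}

# pairwise-concordance AUC: P(score+ > score-) + 0.5 P(tie)
concordance_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
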