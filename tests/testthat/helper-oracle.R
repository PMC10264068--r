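# Independent brute-force oracle for the anticodon-arm finder: scores every
# possible loop placement directly, with the same pair set, thresholds and
# tie-breaks, written as a plain double loop with no shared code path.

oracle_arm <- function(sequence, anticodon = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  pairs <- c("AT", "TA", "GC", "CG", "GT", "TG")
  threshold <- if (is.null(anticodon)) 4L else 3L
  best <- NULL
  for (L in 5:(n - 12)) {
    loop <- substr(sequence, L + 1, L + 7)
    if (!is.null(anticodon) && substr(loop, 3, 5) != toupper(anticodon)) next
    s5 <- strsplit(substr(sequence, L - 4, L), "")[[1]]
    s3 <- strsplit(substr(sequence, L + 8, L + 12), "")[[1]]
    pc <- 0L
    for (k in 1:5) if (paste0(s5[k], s3[6 - k]) %in% pairs) pc <- pc + 1L
    if (pc < threshold) next
    cand <- list(loop_start = L, pairing_count = pc, dist = abs(L - 0.42 * n))
    if (is.null(best) ||
        pc > best$pairing_count ||
        (pc == best$pairing_count && cand$dist < best$dist) ||
        (pc == best$pairing_count && cand$dist == best$dist &&
         L < best$loop_start)) {
      best <- cand
    }
  }
  best
}

# Random sequence with one planted perfectly paired arm; the hint is the
# planted anticodon (which may occur elsewhere by chance -- both searcher and
# oracle must resolve such cases identically).
random_planted_arm <- function(seed) {
  set.seed(seed)
  n <- sample(60:95, 1)
  seqv <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  L <- sample(5:(n - 12), 1)
  stem5 <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seqv[(L - 4):L] <- stem5
  seqv[(L + 8):(L + 12)] <- rev(unname(comp[stem5]))
  list(sequence = paste(seqv, collapse = ""),
       anticodon = paste(seqv[(L + 3):(L + 5)], collapse = ""))
}
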