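# deterministic 120-case fixture: 100 cases engineered into the possible
# band (scores 1-4) and 20 into the probable band (scores 5-8), mirroring
# a case-by-case causality review split
naranjo_fixture <- function() {
  possible <- lapply(1:100, function(i) {
    # scores cycle through 1..4 via yes-counts on +1 questions
    k <- (i %% 4) + 1
    ans <- rep("unknown", 10)
    ans[c(1, 3, 7, 8)[seq_len(k)]] <- "yes"
    ans
  })
  probable <- lapply(1:20, function(i) {
    ans <- rep("unknown", 10)
    ans[c(2, 4)] <- "yes"                # +2 each (rechallenge, onset)
    ans[c(1, 3, 7)[seq_len((i %% 3) + 1)]] <- "yes"  # scores 5..7
    ans
  })
  all_ans <- c(possible, probable)
  df <- as.data.frame(do.call(rbind, lapply(all_ans, function(a) a)),
                      stringsAsFactors = FALSE)
  names(df) <- paste0("q", 1:10)
  tibble::as_tibble(cbind(case_id = sprintf("CASE%03d", 1:120), df))
}

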