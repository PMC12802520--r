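# Independent scalar transliterations of the published 2x2 formulas,
# kept deliberately separate from the package's vectorized code path.
oracle_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  T_ <- a + b + c + d
  s <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- (a * d) / (b * c)
  prr <- (a * (c + d)) / (c * (a + b))
  chi2 <- ((a * d - b * c)^2) * T_ / ((a + b) * (c + d) * (a + c) * (b + d))
  ic <- log(a * T_ / ((a + c) * (a + b)), base = 2)
  ebgm <- a * T_ / ((a + c) * (a + b))
  list(
    s = s,
    ror = ror,
    ror_low = exp(log(ror) - 1.96 * s),
    ror_high = exp(log(ror) + 1.96 * s),
    prr = prr,
    prr_low = exp(log(prr) - 1.96 * s),
    prr_high = exp(log(prr) + 1.96 * s),
    chi2 = chi2,
    ic = ic,
    ic025 = if (ic > 0) exp(log(ic) - 1.96 * s) else NA_real_,
    ebgm = ebgm,
    ebgm05 = exp(log(ebgm) - 1.64 * s)
  )
}

# Naive double-loop recount of every 2x2 table for a drug: the oracle for
# build_all_tables. Intentionally slow and simple.
brute_tables <- function(reports, drug) {
  n <- nrow(reports)
  is_ps <- logical(n)
  for (i in seq_len(n)) {
    d <- reports$drugs[[i]]
    is_ps[i] <- any(names(d) == "primary_suspect" &
                      tolower(unname(d)) == tolower(drug))
  }
  pts <- unique(unlist(reports$pts[is_ps]))
  pts <- sort(pts)
  out <- lapply(pts, function(pt) {
    a <- b <- cc <- dd <- 0L
    for (i in seq_len(n)) {
      has_pt <- pt %in% reports$pts[[i]]
      if (is_ps[i] && has_pt) a <- a + 1L
      else if (is_ps[i]) b <- b + 1L
      else if (has_pt) cc <- cc + 1L
      else dd <- dd + 1L
    }
    data.frame(drug = drug, pt = pt, a = a, b = b, c = cc, d = dd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Small simulation configuration used across tests: the demo vocabularies
# (drug of interest with a 5% primary-suspect share) plus optional planting.
test_config <- function(n_cases, seed, planted = NULL, ...) {
  planted <- planted %||% tibble::tibble(drug = character(), pt = character(),
                                         lambda = numeric())
  sim_config(n_cases = n_cases, planted = planted, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
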