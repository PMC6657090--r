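# internal helpers shared across modules

# round-half-up at `digits` decimals; base round() is round-half-even
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single non-negative integer", name),
         call. = FALSE)
  }
  as.integer(x)
}

# concatenate GRanges after unifying their seqlevels
.bindGr <- function(...) {
  grl <- list(...)
  grl <- grl[!vapply(grl, is.null, TRUE)]
  sl <- unique(unlist(lapply(grl, GenomeInfoDb::seqlevels)))
  grl <- lapply(grl, function(g) {
    GenomeInfoDb::seqlevels(g) <- sl
    g
  })
  do.call(c, grl)
}

# derive a component sub-seed from the master seed; kept < 2^31
.subSeed <- function(seed, component) {
  offsets <- c(cohort = 101L, tracks = 211L, longread = 307L,
               expression = 401L, genotypes = 503L)
  stopifnot(component %in% names(offsets))
  (as.integer(seed) * 1009L + offsets[[component]]) %% 2147483647L
}
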