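# Independent brute-force oracles, written directly against
# Biostrings::GENETIC_CODE so they share no code path with the package.

.GC <- Biostrings::GENETIC_CODE
.oracleFams <- local({
  aas <- setdiff(unique(.GC), "*")
  fams <- lapply(aas, function(a) sort(names(.GC)[.GC == a]))
  names(fams) <- aas
  fams
})
.senseOracle <- sort(names(.GC)[.GC != "*"])

countsOf <- function(codons) {
  cnt <- stats::setNames(numeric(length(.senseOracle)), .senseOracle)
  if (length(codons)) {
    tb <- table(codons)
    cnt[names(tb)] <- tb
  }
  cnt
}

naiveEnc <- function(codons, estimator = "plugin") {
  cnt <- countsOf(codons)
  n1 <- 0
  classN <- c(`2` = 0, `3` = 0, `4` = 0, `6` = 0)
  classF <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(.oracleFams)) {
    fam <- .oracleFams[[aa]]
    n <- sum(cnt[fam])
    if (n == 0) next
    if (length(fam) == 1) { n1 <- n1 + 1; next }
    key <- as.character(length(fam))
    classN[key] <- classN[key] + 1
    p <- cnt[fam] / n
    S <- sum(p^2)
    Fa <- if (estimator == "plugin") S else {
      if (n < 2) NA_real_ else (n * S - 1) / (n - 1)
    }
    if (!is.na(Fa)) classF[[key]] <- c(classF[[key]], Fa)
  }
  Fbar <- vapply(classF, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
  if (classN["3"] > 0 && is.na(Fbar["3"]) &&
      !is.na(Fbar["2"]) && !is.na(Fbar["4"]))
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  tot <- n1
  any <- FALSE
  for (k in names(classN)) {
    if (classN[k] > 0 && !is.na(Fbar[k]) && Fbar[k] > 0) {
      tot <- tot + classN[k] / Fbar[k]
      any <- TRUE
    }
  }
  if (!any) return(NA_real_)
  min(tot, 61)
}

naiveCai <- function(codons, refCounts) {
  logs <- c()
  for (cod in codons) {
    aa <- .GC[[cod]]
    if (aa == "*") next
    fam <- .oracleFams[[aa]]
    if (length(fam) == 1) next
    m <- max(refCounts[fam])
    w <- if (m == 0) 1 else max(refCounts[[cod]], 0.5) / m
    logs <- c(logs, log(w))
  }
  if (length(logs) == 0) return(NA_real_)
  exp(mean(logs))
}

naiveCousin <- function(queryCounts, refCounts) {
  nums <- dens <- wts <- c()
  for (aa in names(.oracleFams)) {
    fam <- .oracleFams[[aa]]
    k <- length(fam)
    if (k == 1) next
    nq <- sum(queryCounts[fam])
    nr <- sum(refCounts[fam])
    if (nq == 0 || nr == 0) next
    fr <- refCounts[fam] / nr
    fq <- queryCounts[fam] / nq
    e <- 1 / k
    den <- sum(fr * (fr - e))
    if (den <= 0) next
    nums <- c(nums, sum(fq * (fr - e)))
    dens <- c(dens, den)
    wts <- c(wts, nq)
  }
  if (length(nums) == 0)
    return(list(cousin18 = NA_real_, cousin59 = NA_real_))
  list(cousin18 = mean(nums / dens),
       cousin59 = sum(wts * nums) / sum(wts * dens))
}

# exact two-sided rank-sum p by enumerating all assignments of pooled ranks
exactWilcoxonP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  ws <- apply(idx, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  ew <- nx * ny / 2
  mean(abs(ws - ew) >= abs(wObs - ew) - 1e-9)
}

randomCodons <- function(n, weights = NULL) {
  sample(.senseOracle, n, replace = TRUE, prob = weights)
}

# a small biased reference table shared across tests
toyBiasedRef <- function(seed = 42) {
  set.seed(seed)
  cnt <- stats::setNames(sample(1:50, length(.senseOracle), replace = TRUE),
                         .senseOracle)
  codonUsageTable(cnt, label = "toy_ref")
}

writeTempFasta <- function(seqs, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".fna")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
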