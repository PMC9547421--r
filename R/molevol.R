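# Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction, and
# the Ks -> divergence-time conversion T = Ks/(2 * lambda) with the grass
# synonymous substitution rate lambda = 6.5e-9 per site per year.

validate_cds <- function(cds, what = "cds") {
  validate_sequence(cds, c("A", "C", "G", "T"), what)
  if (nchar(cds) %% 3 != 0)
    stop(what, " length must be divisible by 3")
  gc <- genetic_code()
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  stops <- which(gc[codons] == "*")
  if (length(stops))
    stop("in-frame stop codon at codon index ", stops[1], " of ", what)
  codons
}

# Fraction of synonymous sites per codon: each position contributes
# (number of the 3 single-nucleotide changes that are synonymous)/3.
# Changes creating stop codons are never synonymous and are skipped.
codon_syn_sites <- function(codon) {
  gc <- genetic_code()
  aa <- gc[[codon]]
  ch <- seq_chars(codon)
  s <- 0
  for (i in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == ch[i]) next
      v <- ch; v[i] <- b
      vc <- paste(v, collapse = "")
      if (gc[[vc]] != "*" && gc[[vc]] == aa) s <- s + 1 / 3
    }
  }
  s
}

#' Count synonymous and nonsynonymous sites of a coding sequence
#'
#' NG86 site counting: `S` is the sum over codon positions of the fraction
#' of single-nucleotide changes that are synonymous; `N = 3 * codons - S`,
#' so `S + N` equals the nucleotide length exactly.
#'
#' @param cds Coding sequence over `A`/`C`/`G`/`T`, length divisible by 3,
#'   no in-frame stop.
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @export
count_sites <- function(cds) {
  codons <- validate_cds(cds)
  S <- sum(vapply(codons, codon_syn_sites, numeric(1)))
  c(S = S, N = 3 * length(codons) - S)
}

# Enumerate all orderings of the differing positions between two codons and
# average synonymous/nonsynonymous step tallies over the orderings whose
# intermediate codons are not stops. Returns c(sd, nd, n_valid_paths).
codon_path_counts <- function(ca, cb) {
  gc <- genetic_code()
  pos <- which(seq_chars(ca) != seq_chars(cb))
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0, paths = 1))
  perms <- switch(k,
                  `1` = list(1L),
                  `2` = list(c(1L, 2L), c(2L, 1L)),
                  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sd_tot <- 0; nd_tot <- 0; valid <- 0
  cb_ch <- seq_chars(cb)
  for (perm in perms) {
    cur <- seq_chars(ca)
    sd <- 0; nd <- 0; ok <- TRUE
    for (step in perm) {
      prev <- paste(cur, collapse = "")
      cur[pos[step]] <- cb_ch[pos[step]]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[prev]]) sd <- sd + 1 else nd <- nd + 1
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
              valid <- valid + 1 }
  }
  if (valid == 0L) return(c(sd = NA_real_, nd = NA_real_, paths = 0))
  c(sd = sd_tot / valid, nd = nd_tot / valid, paths = valid)
}

#' Count synonymous and nonsynonymous differences between two coding
#' sequences
#'
#' NG86 pathway counting: for each codon pair differing at `k` positions,
#' the synonymous/nonsynonymous tallies are averaged over all `k!` orderings
#' of single-nucleotide steps, excluding orderings that pass through a stop
#' codon (the remaining orderings are renormalized). Codons whose every
#' path hits a stop are excluded with a warning and counted in the
#' `dropped` attribute.
#'
#' @param cds_a,cds_b Codon-aligned coding sequences of equal length.
#' @return Named numeric vector `c(Sd = ..., Nd = ...)` with attribute
#'   `dropped` (number of excluded codons).
#' @export
count_differences <- function(cds_a, cds_b) {
  ca <- validate_cds(cds_a, "cds_a")
  cb <- validate_cds(cds_b, "cds_b")
  if (length(ca) != length(cb))
    stop("sequences must have equal length")
  sd <- 0; nd <- 0; dropped <- 0L
  for (i in seq_along(ca)) {
    r <- codon_path_counts(ca[i], cb[i])
    if (r[["paths"]] == 0) {
      dropped <- dropped + 1L
      next
    }
    sd <- sd + r[["sd"]]; nd <- nd + r[["nd"]]
  }
  if (dropped > 0L)
    warning(dropped, " codon(s) excluded: every mutational path passes ",
            "through a stop codon")
  structure(c(Sd = sd, Nd = nd), dropped = dropped)
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori Ka/Ks estimate for a codon-aligned pair
#'
#' Computes NG86 site and difference counts (sites averaged over the two
#' sequences), the proportions `ps = Sd/S` and `pn = Nd/N`, Jukes-Cantor
#' corrected distances `Ks` and `Ka`, the ratio `omega = Ka/Ks`, and the
#' divergence time in Mya via [divergence_time()]. A proportion `>= 3/4`
#' makes the corrected distance undefined (flagged, not an error); `omega`
#' is undefined when `Ks` is undefined or zero.
#'
#' @param cds_a,cds_b Codon-aligned coding sequences.
#' @param lambda_rate Synonymous substitution rate per site per year used
#'   for the time conversion (default `6.5e-9`).
#' @return Object of class `kaks_result`: list with `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ka`, `Ks`, `omega`, `omega_defined`, `t_mya`, `method`,
#'   `dropped_codons`.
#' @export
kaks <- function(cds_a, cds_b, lambda_rate = 6.5e-9) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences must have equal length")
  sites_a <- count_sites(cds_a)
  sites_b <- count_sites(cds_b)
  S <- (sites_a[["S"]] + sites_b[["S"]]) / 2
  N <- (sites_a[["N"]] + sites_b[["N"]]) / 2
  d <- count_differences(cds_a, cds_b)
  ps <- if (S > 0) d[["Sd"]] / S else 0
  pn <- if (N > 0) d[["Nd"]] / N else 0
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  omega_defined <- !is.na(Ks) && Ks > 0 && !is.na(Ka)
  omega <- if (omega_defined) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = d[["Sd"]], Nd = d[["Nd"]],
                 ps = ps, pn = pn, Ka = Ka, Ks = Ks,
                 omega = omega, omega_defined = omega_defined,
                 t_mya = divergence_time(Ks, lambda_rate),
                 method = "NG86-JC",
                 dropped_codons = attr(d, "dropped")),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka/Ks (%s): S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
              x$method, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ka=%s Ks=%s omega=%s T=%s Mya\n",
              format(x$Ka), format(x$Ks),
              if (x$omega_defined) format(x$omega) else "undefined",
              format(x$t_mya)))
  invisible(x)
}

#' Convert a synonymous distance to a divergence time
#'
#' `T = Ks / (2 * lambda * 1e6)` Mya, i.e. `Ks/(2 * lambda)` years expressed
#' in millions. With the default grass rate `lambda = 6.5e-9`, `Ks = 0.013`
#' corresponds to 1 Mya.
#'
#' @param ks Synonymous substitutions per synonymous site (`NA` propagates).
#' @param lambda_rate Substitution rate per site per year.
#' @return Time in Mya.
#' @export
divergence_time <- function(ks, lambda_rate = 6.5e-9) {
  if (length(ks) == 1L && is.na(ks)) return(NA_real_)
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be non-negative")
  ks / (2 * lambda_rate * 1e6)
}

#' Classify the selection regime from a Ka/Ks result
#'
#' @param result A `kaks_result` object (or a bare omega value).
#' @param tol Tolerance around 1 for the neutral call.
#' @return One of `"purifying"`, `"neutral"`, `"positive"`, `"undefined"`.
#' @export
selection_call <- function(result, tol = 1e-9) {
  omega <- if (inherits(result, "kaks_result")) {
    if (!result$omega_defined) return("undefined")
    result$omega
  } else result
  if (is.na(omega)) return("undefined")
  if (abs(omega - 1) <= tol) "neutral"
  else if (omega < 1) "purifying"
  else "positive"
}
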