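# Physicochemical protein characterization from sequence alone: average
# molecular weight, Kyte-Doolittle GRAVY, Ikai aliphatic index, Guruprasad
# instability index, Henderson-Hasselbalch isoelectric point, and atomic
# composition. Every underlying scale ships as a versioned data file under
# inst/extdata, so adopting a different convention is a configuration
# change, not a code change.

.pp_env <- new.env(parent = emptyenv())

pp_table <- function(name) {
  if (is.null(.pp_env[[name]])) {
    .pp_env[[name]] <- utils::read.delim(extdata(paste0(name, ".tsv")),
                                         stringsAsFactors = FALSE)
  }
  .pp_env[[name]]
}

validate_protein_strict <- function(seq) {
  ch <- validate_sequence(seq, AA_ALPHABET, "protein sequence")
  x <- which(ch == "X")
  if (length(x))
    stop("ambiguous residue X at position ", x[1],
         "; physicochemical properties require fully specified sequences")
  ch
}

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.01524 Da).
#'
#' @param seq Amino-acid string (no `X`).
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(seq) {
  ch <- validate_protein_strict(seq)
  tab <- pp_table("residue_masses")
  masses <- stats::setNames(tab$avg_mass, tab$residue)
  sum(masses[ch]) + WATER_MASS
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue Kyte-Doolittle hydropathy values.
#'
#' @param seq Amino-acid string (no `X`).
#' @return Mean hydropathy (dimensionless).
#' @export
gravy <- function(seq) {
  ch <- validate_protein_strict(seq)
  tab <- pp_table("kyte_doolittle")
  vals <- stats::setNames(tab$hydropathy, tab$residue)
  mean(vals[ch])
}

#' Aliphatic index
#'
#' Ikai's relative volume of aliphatic side chains:
#' `AI = X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu)` with `X` the mole
#' percentages.
#'
#' @param seq Amino-acid string (no `X`).
#' @return Aliphatic index (dimensionless).
#' @export
aliphatic_index <- function(seq) {
  ch <- validate_protein_strict(seq)
  L <- length(ch)
  molpct <- function(a) 100 * sum(ch == a) / L
  molpct("A") + 2.9 * molpct("V") + 3.9 * (molpct("I") + molpct("L"))
}

#' Instability index
#'
#' Guruprasad dipeptide instability-weight sum: `(10/L) * sum(DIWV)` over
#' the `L - 1` consecutive dipeptides. Values strictly greater than 40
#' classify the protein as unstable.
#'
#' @param seq Amino-acid string of length >= 2 (no `X`).
#' @return Instability index with attribute `unstable` (logical).
#' @export
instability_index <- function(seq) {
  ch <- validate_protein_strict(seq)
  L <- length(ch)
  if (L < 2L) stop("instability index requires at least 2 residues")
  tab <- pp_table("diwv")
  rownames(tab) <- tab$first
  m <- as.matrix(tab[, -1, drop = FALSE])
  v <- sum(m[cbind(ch[-L], ch[-1])]) * 10 / L
  structure(v, unstable = v > 40)
}

# Net charge at a given pH (Henderson-Hasselbalch over termini and the
# ionizable side chains); strictly decreasing in pH.
net_charge <- function(ch, pH, pka) {
  pos <- pka[pka$charge == "positive", ]
  neg <- pka[pka$charge == "negative", ]
  q <- 0
  for (i in seq_len(nrow(pos))) {
    n <- if (pos$group[i] == "Nterm") 1 else sum(ch == pos$group[i])
    if (n > 0) q <- q + n / (1 + 10^(pH - pos$pka[i]))
  }
  for (i in seq_len(nrow(neg))) {
    n <- if (neg$group[i] == "Cterm") 1 else sum(ch == neg$group[i])
    if (n > 0) q <- q - n / (1 + 10^(neg$pka[i] - pH))
  }
  q
}

#' Theoretical isoelectric point
#'
#' Bisection root of the net-charge curve over pH 0-14, using the
#' EMBOSS-style pKa set shipped with the package (N-terminus 8.6,
#' C-terminus 3.6, side chains C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
#' Y 10.1). The net charge is strictly monotone in pH, so the root is
#' unique.
#'
#' @param seq Amino-acid string (no `X`).
#' @param tol Bisection tolerance in pH units.
#' @return pH at which the net charge is zero.
#' @export
isoelectric_point <- function(seq, tol = 1e-3) {
  ch <- validate_protein_strict(seq)
  pka <- pp_table("pka_emboss")
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(ch, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Atomic composition of a protein
#'
#' Sums the free-amino-acid formulas and removes one water (`H2O`) per
#' peptide bond.
#'
#' @param seq Amino-acid string (no `X`).
#' @return Named integer vector of `C`, `H`, `N`, `O`, `S` counts.
#' @export
atomic_composition <- function(seq) {
  ch <- validate_protein_strict(seq)
  tab <- pp_table("residue_atoms")
  rownames(tab) <- tab$residue
  m <- as.matrix(tab[ch, c("C", "H", "N", "O", "S"), drop = FALSE])
  counts <- colSums(m)
  L <- length(ch)
  counts["H"] <- counts["H"] - 2L * (L - 1L)
  counts["O"] <- counts["O"] - (L - 1L)
  stats::setNames(as.integer(counts), c("C", "H", "N", "O", "S"))
}

#' Full physicochemical characterization of a protein set
#'
#' @param records Protein data frame (columns `id`, `sequence`).
#' @return Data frame with one row per protein: `id`, `length`, `mw`, `pi`,
#'   `gravy`, `aliphatic_index`, `instability_index`, `unstable`, and atom
#'   counts `C`, `H`, `N`, `O`, `S`.
#' @export
protein_properties <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    s <- records$sequence[i]
    ii <- instability_index(s)
    at <- atomic_composition(s)
    data.frame(id = records$id[i], length = nchar(s),
               mw = molecular_weight(s), pi = isoelectric_point(s),
               gravy = gravy(s), aliphatic_index = aliphatic_index(s),
               instability_index = as.numeric(ii),
               unstable = attr(ii, "unstable"),
               C = at[["C"]], H = at[["H"]], N = at[["N"]], O = at[["O"]],
               S = at[["S"]])
  })
  do.call(rbind, rows)
}
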