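# Promoter extraction and IUPAC cis-regulatory element censusing.

IUPAC_DNA <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

iupac_expand <- function(code) {
  s <- IUPAC_DNA[[code]]
  if (is.null(s)) stop("invalid IUPAC code: ", code)
  s
}

reverse_complement_iupac <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  ch <- comp[rev(seq_chars(pattern))]
  if (any(is.na(ch))) stop("invalid IUPAC code in pattern: ", pattern)
  paste(ch, collapse = "")
}

#' Default cis-regulatory motif table
#'
#' Loads the curated IUPAC motif table shipped with the package
#' (PLACE/PlantCARE-style patterns for ABRE, DRE, MBS, LTR, G-box, ARE,
#' TC-rich, WUN-motif, RY-element, TGA-element, Sp1). The table is an
#' editable input, not fixed biological truth; each entry records its
#' provenance.
#'
#' @return Data frame with columns `name`, `category`, `pattern`,
#'   `provenance`.
#' @export
default_motif_table <- function() {
  read_motif_table(extdata("motifs.json"))
}

#' Read a motif table from JSON
#'
#' @param path JSON file with a top-level `motifs` array of
#'   `{name, category, pattern}` objects.
#' @return Data frame as in [default_motif_table()]; patterns are validated
#'   against the IUPAC alphabet at load time.
#' @export
read_motif_table <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tab <- raw$motifs
  stopifnot(all(c("name", "category", "pattern") %in% names(tab)))
  if (anyDuplicated(tab$name)) stop("duplicate motif name in table")
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(tab$pattern[i])) stop("empty pattern for ", tab$name[i])
    for (code in seq_chars(tab$pattern[i])) {
      if (is.null(IUPAC_DNA[[code]]))
        stop("invalid IUPAC code '", code, "' in motif ", tab$name[i])
    }
  }
  if (is.null(tab$provenance)) tab$provenance <- NA_character_
  tab[, c("name", "category", "pattern", "provenance")]
}

#' Extract upstream promoter windows
#'
#' For a plus-strand gene the window is the `length` bases ending at the
#' annotated gene start; for a minus-strand gene, the `length` bases
#' following the gene end, reverse-complemented. Windows are clipped at
#' contig edges and flagged as truncated.
#'
#' @param genes Gene-model data frame (0-based half-open, as from
#'   [read_gff3()]).
#' @param genome Named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param length Window length in bp (default 1500, i.e. 1.5 kb upstream of
#'   the start codon).
#' @return Data frame `gene_id`, `sequence`, `actual_length`, `truncated`.
#' @export
extract_upstream <- function(genes, genome, length = 1500L) {
  stopifnot(length > 0L)
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chromosome[i]
    if (!(chrom %in% names(genome)))
      stop("chromosome '", chrom, "' of gene ", genes$gene_id[i],
           " absent from the genome")
    contig <- genome[[chrom]]
    L <- nchar(contig)
    if (genes$strand[i] == "+") {
      e <- genes$start[i]
      s <- max(0L, e - length)
      win <- substr(contig, s + 1L, e)
    } else {
      s <- genes$end[i]
      e <- min(L, s + length)
      win <- substr(contig, s + 1L, e)
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(win)))
    }
    out[[i]] <- data.frame(gene_id = genes$gene_id[i], sequence = win,
                           actual_length = nchar(win),
                           truncated = nchar(win) < length)
  }
  do.call(rbind, out)
}

#' Scan a sequence for IUPAC motif occurrences on both strands
#'
#' Every position on both strands is tested against each pattern
#' (degenerate IUPAC codes in the pattern match their letter sets; `N` in
#' the subject matches nothing). A minus-strand hit is reported at the
#' 0-based forward-strand start of the matched window, so a palindromic
#' motif yields one hit per strand at the same locus.
#'
#' @param seq Nucleotide string over `A`/`C`/`G`/`T`/`N`.
#' @param motif_table Motif table (default [default_motif_table()]).
#' @return Data frame `motif`, `start` (0-based forward coordinates),
#'   `strand`, `match` (the forward-strand window).
#' @export
scan_motifs <- function(seq, motif_table = default_motif_table()) {
  validate_sequence(seq, DNA_ALPHABET, "nucleotide sequence")
  subject <- Biostrings::DNAString(seq)
  res <- list()
  for (i in seq_len(nrow(motif_table))) {
    pat <- motif_table$pattern[i]
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else reverse_complement_iupac(pat)
      m <- Biostrings::matchPattern(p, subject,
                                    fixed = c(pattern = FALSE,
                                              subject = TRUE))
      if (length(m) == 0L) next
      starts <- BiocGenerics::start(m) - 1L
      windows <- as.character(m)
      keep <- !grepl("N", windows, fixed = TRUE)
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        motif = motif_table$name[i], start = starts[keep], strand = strand,
        match = windows[keep])
    }
  }
  if (!length(res))
    return(data.frame(motif = character(), start = integer(),
                      strand = character(), match = character()))
  out <- do.call(rbind, res)
  out[order(out$start, out$motif, out$strand), , drop = FALSE]
}

#' Census cis-regulatory elements over a gene set
#'
#' Distinguishes presence (number of genes with at least one occurrence of
#' a motif, with one-decimal half-up percentage of `n_genes`) from
#' occurrence counts, and aggregates per motif category.
#'
#' @param hits Data frame with columns `gene_id`, `motif` (one row per
#'   occurrence), e.g. the row-bound results of [scan_motifs()] per gene.
#' @param n_genes Number of genes surveyed (presence denominator).
#' @param motif_table Motif table used for the scan.
#' @return List with `per_motif` (`motif`, `category`, `genes_present`,
#'   `percent`, `occurrences`), `per_category` (`category`, `types_present`,
#'   `occurrences`), `total_types`, `total_occurrences`, `n_genes`.
#' @export
element_census <- function(hits, n_genes,
                           motif_table = default_motif_table()) {
  per <- lapply(seq_len(nrow(motif_table)), function(i) {
    nm <- motif_table$name[i]
    h <- hits[hits$motif == nm, , drop = FALSE]
    present <- length(unique(h$gene_id))
    data.frame(motif = nm, category = motif_table$category[i],
               genes_present = present,
               percent = if (n_genes > 0)
                 census_percentage(present, n_genes) else 0,
               occurrences = nrow(h))
  })
  per_motif <- do.call(rbind, per)
  agg <- stats::aggregate(cbind(types_present = occurrences > 0,
                                occurrences = occurrences) ~ category,
                          data = per_motif, FUN = sum)
  list(per_motif = per_motif, per_category = agg,
       total_types = sum(per_motif$occurrences > 0),
       total_occurrences = sum(per_motif$occurrences),
       n_genes = n_genes)
}
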