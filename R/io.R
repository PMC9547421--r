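# Readers and writers for the standard formats the pipeline consumes, plus
# chromosome bookkeeping. Internal coordinates are 0-based half-open
# everywhere; GFF3 I/O converts at the boundary and user-facing reports print
# 1-based inclusive.

#' Read a protein or nucleotide FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] with the validation the pipeline
#' relies on: sequences are uppercased, wrapped lines are joined, record ids
#' (the first whitespace-delimited token of each header) must be unique, and
#' every character must belong to the declared alphabet (20 amino acids plus
#' X, or A/C/G/T/N for nucleotides).
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` or `"dna"`.
#' @return A data frame with columns `id`, `sequence`, `source_note` (the
#'   original full header line).
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", dup[1])
  seqs <- toupper(as.character(set))
  alphabet <- if (type == "protein") AA_ALPHABET else DNA_ALPHABET
  for (i in seq_along(seqs)) {
    ch <- seq_chars(seqs[i])
    bad <- which(!(ch %in% alphabet))
    if (length(bad))
      stop(sprintf("record '%s': invalid character '%s' at position %d",
                   ids[i], ch[bad[1]], bad[1]))
  }
  data.frame(id = ids, sequence = unname(seqs), source_note = headers,
             row.names = NULL)
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports the annotation with [rtracklayer::import()] and keeps only
#' features of type `gene`. Coordinates are converted from GFF3's 1-based
#' inclusive convention to the package-internal 0-based half-open one.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `gene_id`, `chromosome`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"` or `"-"`).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error: ",
                                          conditionMessage(e), call. = FALSE))
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | !nzchar(ids)))
    stop("gene feature without an ID attribute at record ",
         which(is.na(ids) | !nzchar(ids))[1])
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!(strand %in% c("+", "-"))))
    stop("gene feature with missing strand: ", ids[!(strand %in% c("+", "-"))][1])
  data.frame(gene_id = ids,
             chromosome = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = strand)
}

#' Write gene models to GFF3
#'
#' @param genes Data frame as returned by [read_gff3()] (0-based half-open).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    writeLines(paste(genes$chromosome[i], "ringzf", "gene",
                     genes$start[i] + 1L, genes$end[i], ".", genes$strand[i],
                     ".", paste0("ID=", genes$gene_id[i]), sep = "\t"), con)
  }
  invisible(path)
}

parse_homoeologous_group <- function(chromosome) {
  m <- regmatches(chromosome, regexec("^([1-7])([ABD])$", chromosome))
  vapply(seq_along(chromosome), function(i) {
    if (length(m[[i]]) == 3L) m[[i]][2] else "Un"
  }, character(1))
}

#' Tabulate genes per chromosome or per homoeologous group
#'
#' Hexaploid wheat chromosomes are named `1A`..`7D`; homoeologous grouping
#' maps `nA`/`nB`/`nD` to group `n` and anything unplaced (or unparseable,
#' with a warning) to `"Un"`.
#'
#' @param genes Gene-model data frame with a `chromosome` column.
#' @param grouping `"by_homoeologous_group"` or `"by_chromosome"`.
#' @return Data frame with columns `group` and `count`, ordered groups 1..7
#'   then `"Un"` (or chromosome labels in that group order). Counts always
#'   sum to `nrow(genes)`.
#' @export
chromosome_distribution <- function(genes,
                                    grouping = c("by_homoeologous_group",
                                                 "by_chromosome")) {
  grouping <- match.arg(grouping)
  chrom <- as.character(genes$chromosome)
  if (nrow(genes) > 0 && any(is.na(chrom) | !nzchar(chrom)))
    stop("every gene must carry a non-empty chromosome label")
  grp <- parse_homoeologous_group(chrom)
  odd <- chrom[grp == "Un" & chrom != "Un"]
  if (length(odd))
    warning("unparseable chromosome label(s) assigned to 'Un': ",
            paste(unique(odd), collapse = ", "))
  if (grouping == "by_homoeologous_group") {
    levels <- c(as.character(1:7), "Un")
    counts <- table(factor(grp, levels = levels))
  } else {
    levels <- c(paste0(rep(1:7, each = 3), c("A", "B", "D")), "Un")
    lab <- ifelse(grp == "Un", "Un", chrom)
    counts <- table(factor(lab, levels = levels))
  }
  data.frame(group = names(counts), count = as.integer(counts),
             row.names = NULL)
}
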