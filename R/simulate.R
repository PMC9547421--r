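# Synthetic-data generators. Every input the pipeline consumes can be
# simulated with planted ground truth, so each stage is testable end to end
# without external downloads. All generators are pure functions of their
# arguments including the seed.

# Spacer/flank filler residues that can never act as a ligand for any slot
# of the default rules (no C, H, M, R, D), so planted domains are provably
# the only rule matches in a generated protein.
FILLER_AA <- c("A", "G", "L", "S", "T", "V", "P", "E", "Q", "N")

random_filler <- function(n) {
  if (n <= 0) return("")
  paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")
}

# uniform draw from an inclusive integer range (safe for degenerate ranges,
# unlike sample(n, 1))
sample_range <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L

#' Generate one protein containing a planted RING domain
#'
#' Builds a sequence whose only rule match is a single planted domain of the
#' requested subtype: ligand residues are drawn from the rule's allowed
#' sets, spacers and flanks from a ligand-free filler alphabet.
#'
#' @param subtype Rule name present in `rule_table` (e.g. `"RING-M"`).
#' @param spacers Vector of 7 spacer lengths (8 for IBR), or `"sample"` to
#'   draw each uniformly from the rule's range.
#' @param flank_lengths Two integers: residues added before and after the
#'   domain.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param rule_table Rule table (default [default_rule_table()]).
#' @param id Record id.
#' @param filler Filler residue set; the default excludes all possible
#'   ligand residues.
#' @return List with `record` (one-row protein data frame) and `truth`
#'   (list: `protein_id`, `subtype`, `start`, `end`, `positions` 0-based).
#' @export
make_ring_protein <- function(subtype, spacers = "sample",
                              flank_lengths = c(20L, 20L), seed = 1L,
                              rule_table = default_rule_table(),
                              id = paste0(subtype, "_1"),
                              filler = FILLER_AA) {
  names_ <- vapply(rule_table, `[[`, character(1), "name")
  if (!(subtype %in% names_)) stop("unknown subtype: ", subtype)
  rule <- rule_table[[match(subtype, names_)]]
  n_sp <- length(rule$spacers)
  with_seed(seed, {
    if (identical(spacers, "sample")) {
      spacers <- vapply(rule$spacers, sample_range, integer(1))
    } else {
      spacers <- as.integer(spacers)
      if (length(spacers) != n_sp)
        stop("expected ", n_sp, " spacers for rule ", subtype)
      for (i in seq_len(n_sp)) {
        r <- rule$spacers[[i]]
        if (spacers[i] < r[1] || spacers[i] > r[2])
          stop("spacer ", i, " = ", spacers[i], " outside range [",
               r[1], ",", r[2], "] of rule ", subtype)
      }
    }
    ligands <- vapply(rule$allowed,
                      function(a) if (length(a) == 1L) a else sample(a, 1L),
                      character(1))
    fill <- function(n) if (n <= 0) "" else
      paste(sample(filler, n, replace = TRUE), collapse = "")
    core <- ligands[1]
    for (i in seq_len(n_sp)) core <- paste0(core, fill(spacers[i]),
                                            ligands[i + 1L])
    sequence <- paste0(fill(flank_lengths[1]), core, fill(flank_lengths[2]))
    p1 <- flank_lengths[1]
    positions <- p1 + c(0L, cumsum(spacers + 1L))
    list(record = data.frame(id = id, sequence = sequence,
                             source_note = paste0("synthetic ", subtype)),
         truth = list(protein_id = id, subtype = subtype,
                      start = positions[1], end = positions[length(positions)] + 1L,
                      positions = positions, spacers = spacers))
  })
}

#' Generate a synthetic proteome with planted subtype counts
#'
#' Subtype labels may include `RING-HCa` / `RING-HCb`, which plant a
#' `RING-HC` domain whose discriminating spacer (the `X(4-48)` region) is
#' drawn from `[threshold, 48]` or `[4, threshold - 1]` respectively, under
#' the default [split_hc()] criterion. Decoy proteins are built entirely
#' from the ligand-free filler alphabet and therefore contain no rule match.
#'
#' @param counts_per_subtype Named non-negative integer vector, e.g.
#'   `c("RING-H2" = 57, "RING-HCa" = 59, "RING-HCb" = 16, "RING-D" = 3,
#'   "RING-M" = 3)`.
#' @param n_decoys Number of decoy proteins.
#' @param seed Integer seed.
#' @param rule_table Rule table.
#' @param hc_threshold Threshold of the HCa/HCb spacer criterion used for
#'   planting.
#' @return List with `records` (protein data frame) and `truth` (data frame
#'   `protein_id`, `subtype`, `start`, `end`, `positions` comma-joined).
#' @export
make_protein_set <- function(counts_per_subtype, n_decoys = 0L, seed = 1L,
                             rule_table = default_rule_table(),
                             hc_threshold = 8L) {
  if (any(counts_per_subtype < 0)) stop("counts must be non-negative")
  with_seed(seed, {
    records <- list(); truths <- list()
    k <- 0L
    for (lab in names(counts_per_subtype)) {
      for (j in seq_len(counts_per_subtype[[lab]])) {
        k <- k + 1L
        id <- sprintf("syn_%04d", k)
        rule_lab <- lab
        forced <- NULL
        if (lab %in% c("RING-HCa", "RING-HCb")) {
          rule_lab <- "RING-HC"
          rng <- if (lab == "RING-HCa") c(hc_threshold, 48L)
                 else c(4L, hc_threshold - 1L)
          forced <- sample_range(rng)
        }
        sp <- "sample"
        if (!is.null(forced)) {
          names_ <- vapply(rule_table, `[[`, character(1), "name")
          rule <- rule_table[[match(rule_lab, names_)]]
          sp <- vapply(rule$spacers, sample_range, integer(1))
          sp[6] <- forced
        }
        one <- make_ring_protein(rule_lab, spacers = sp,
                                 flank_lengths = sample(5:40, 2L,
                                                        replace = TRUE),
                                 seed = NULL, rule_table = rule_table,
                                 id = id)
        one$truth$subtype <- lab
        records[[k]] <- one$record
        truths[[k]] <- data.frame(
          protein_id = id, subtype = lab, start = one$truth$start,
          end = one$truth$end,
          positions = paste(one$truth$positions, collapse = ","))
      }
    }
    for (j in seq_len(n_decoys)) {
      k <- k + 1L
      records[[k]] <- data.frame(id = sprintf("decoy_%04d", j),
                                 sequence = random_filler(sample(80:300, 1L)),
                                 source_note = "synthetic decoy")
    }
    list(records = do.call(rbind, records),
         truth = if (length(truths)) do.call(rbind, truths) else
           data.frame(protein_id = character(), subtype = character(),
                      start = integer(), end = integer(),
                      positions = character()))
  })
}

# --- codon pairs with controlled divergence --------------------------------

genetic_code <- function() Biostrings::GENETIC_CODE

single_nt_variants <- function(codon) {
  ch <- seq_chars(codon)
  out <- character(0)
  for (i in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b != ch[i]) {
      v <- ch; v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Generate a codon-aligned sequence pair with planted substitutions
#'
#' Sequence A is a random stop-free coding sequence; sequence B differs at
#' exactly `n_syn` codons by one synonymous single-nucleotide change and at
#' `n_nonsyn` codons by one nonsynonymous change (standard genetic code,
#' never creating a stop). At most one substitution is introduced per codon,
#' so pathway averaging in the NG86 counts is unambiguous and
#' `(Sd, Nd) = (n_syn, n_nonsyn)` exactly.
#'
#' @param n_codons Number of codons.
#' @param n_syn,n_nonsyn Planted substitution counts;
#'   `n_syn + n_nonsyn <= n_codons`.
#' @param seed Integer seed.
#' @return List with `pair` (list `id_a`, `id_b`, `cds_a`, `cds_b`) and
#'   `truth` (list `n_syn`, `n_nonsyn`).
#' @export
make_codon_pair <- function(n_codons, n_syn, n_nonsyn, seed = 1L) {
  if (n_syn + n_nonsyn > n_codons)
    stop("n_syn + n_nonsyn must not exceed n_codons")
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  with_seed(seed, {
    codons <- sample(sense, n_codons, replace = TRUE)
    idx <- sample.int(n_codons, n_syn + n_nonsyn)
    syn_idx <- idx[seq_len(n_syn)]
    non_idx <- idx[setdiff(seq_along(idx), seq_len(n_syn))]
    codons_b <- codons
    pick_change <- function(i, synonymous) {
      for (try in 1:100) {
        cod <- codons[i]
        vars <- single_nt_variants(cod)
        vars <- vars[gc[vars] != "*"]
        ok <- if (synonymous) vars[gc[vars] == gc[cod]]
              else vars[gc[vars] != gc[cod]]
        if (length(ok)) return(sample(ok, 1L))
        # codon admits no such change (e.g. ATG/TGG have no synonymous
        # variant): redraw the source codon and retry
        codons[i] <<- sample(sense, 1L)
      }
      stop("could not plant substitution after bounded retries")
    }
    for (i in syn_idx) codons_b[i] <- pick_change(i, TRUE)
    for (i in non_idx) codons_b[i] <- pick_change(i, FALSE)
    # pick_change may have redrawn codons[i]; rebuild B's unchanged codons
    codons_b[setdiff(seq_len(n_codons), idx)] <-
      codons[setdiff(seq_len(n_codons), idx)]
    list(pair = list(id_a = "seq_a", id_b = "seq_b",
                     cds_a = paste(codons, collapse = ""),
                     cds_b = paste(codons_b, collapse = "")),
         truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn))
  })
}

# --- promoters with planted motifs -----------------------------------------

#' Generate a promoter sequence with planted cis-element occurrences
#'
#' The background is drawn from a restricted alphabet (default `A`/`T`) in
#' which no motif of the active table can be spelled -- each motif must
#' contain at least one position whose allowed letters are disjoint from the
#' background alphabet, on both strands; otherwise the generator refuses.
#' Planted occurrences insert a concrete instance of the (possibly
#' degenerate) pattern, reverse-complemented for minus-strand plants. The
#' assembled sequence is verified by [scan_motifs()]: any accidental match
#' spanning a plant boundary triggers background resampling (bounded).
#'
#' @param length Promoter length in bp.
#' @param plant List of plants, each `list(motif, start, strand)` with
#'   0-based non-overlapping starts.
#' @param seed Integer seed.
#' @param motif_table Motif table (default [default_motif_table()]).
#' @param background Background alphabet.
#' @return List with `record` (list `id`, `sequence`) and `truth` (data
#'   frame `motif`, `start`, `strand`).
#' @export
make_promoter <- function(length = 1500L, plant = list(), seed = 1L,
                          motif_table = default_motif_table(),
                          background = c("A", "T")) {
  for (i in seq_along(motif_table$pattern)) {
    for (pat in c(motif_table$pattern[i],
                  reverse_complement_iupac(motif_table$pattern[i]))) {
      sets <- lapply(seq_chars(pat), iupac_expand)
      blocked <- any(vapply(sets, function(s)
        length(intersect(s, background)) == 0L, logical(1)))
      if (!blocked)
        stop("motif ", motif_table$name[i],
             " can be spelled by the background alphabet; ",
             "restrict the background or the motif table")
    }
  }
  plants <- lapply(plant, function(p) {
    i <- match(p$motif, motif_table$name)
    if (is.na(i)) stop("unknown motif: ", p$motif)
    list(motif = p$motif, start = as.integer(p$start),
         strand = p$strand, width = nchar(motif_table$pattern[i]),
         pattern = motif_table$pattern[i])
  })
  if (length(plants)) {
    spans <- do.call(rbind, lapply(plants, function(p)
      c(p$start, p$start + p$width)))
    if (any(spans[, 1] < 0) || any(spans[, 2] > length))
      stop("planted occurrence outside the sequence")
    o <- order(spans[, 1])
    if (any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)]))
      stop("planted occurrences overlap")
  }
  truth <- data.frame(
    motif = vapply(plants, `[[`, character(1), "motif"),
    start = vapply(plants, `[[`, integer(1), "start"),
    strand = vapply(plants, `[[`, character(1), "strand"))
  with_seed(seed, {
    for (attempt in 1:25) {
      ch <- sample(background, length, replace = TRUE)
      for (p in plants) {
        inst <- paste(vapply(lapply(seq_chars(p$pattern), iupac_expand),
                             function(s) if (base::length(s) == 1L) s else
                               sample(s, 1L), character(1)), collapse = "")
        if (p$strand == "-") inst <- reverse_complement_iupac(inst)
        ch[(p$start + 1L):(p$start + p$width)] <- seq_chars(inst)
      }
      sequence <- paste(ch, collapse = "")
      hits <- scan_motifs(sequence, motif_table)
      planted_key <- paste(truth$motif, truth$start)
      ok_hit <- paste(hits$motif, hits$start) %in% planted_key
      strand_ok <- all(paste(truth$motif, truth$start, truth$strand) %in%
                         paste(hits$motif, hits$start, hits$strand))
      if (all(ok_hit) && strand_ok)
        return(list(record = list(id = "promoter_1", sequence = sequence),
                    truth = truth))
    }
    stop("could not assemble a collision-free promoter after 25 attempts; ",
         "use a longer sequence or a smaller motif table")
  })
}

# --- expression matrices ----------------------------------------------------

#' Default developmental-stage and stress-treatment column labels
#'
#' Fifteen developmental stages (tissue x stage combinations from seedling
#' root to late grain) and six stress treatments (drought, heat and combined,
#' at 1 h and 6 h), matching a typical wheat expression-atlas layout.
#' @return Character vector of labels.
#' @export
default_stage_labels <- function() {
  c("SR", "RTLS", "RMS", "S1S", "STNS", "SATS", "SL", "LTTS", "L2DAAs",
    "SPTNS", "SPMS", "SPAS", "G2DAAs", "G14DAAs", "G30DAAs")
}

#' @rdname default_stage_labels
#' @export
default_treatment_labels <- function() {
  c("D1h", "D6h", "H1h", "H6h", "DH1h", "DH6h")
}

#' Generate a TPM expression matrix with planted expression groups
#'
#' Group 1 genes are constitutively high across all developmental stages,
#' Group 2 constitutively low; Group 3 genes are induced (basal under
#' control, elevated under every stress treatment) and Group 4 repressed.
#' Genes labeled `"ungrouped"` sit at an intermediate flat level.
#' Multiplicative lognormal noise with the stated coefficient of variation
#' is applied to every cell.
#'
#' @param n_per_group Named counts, e.g. `c(Group1 = 22, Group2 = 47,
#'   ungrouped = 10)`.
#' @param stages Stage column labels (role `"stage"`).
#' @param treatments Treatment column labels (role `"treatment"`); a single
#'   `"Control"` column (role `"control"`) is always added.
#' @param levels Named numeric: `high_tpm`, `low_tpm`, `induced_tpm`,
#'   `basal_tpm`.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return List with `values` (genes x conditions TPM matrix carrying a
#'   `col_roles` attribute), `roles` (named character vector) and `truth`
#'   (named group labels).
#' @export
make_expression_matrix <- function(n_per_group,
                                   stages = default_stage_labels(),
                                   treatments = default_treatment_labels(),
                                   levels = c(high_tpm = 50, low_tpm = 0.2,
                                              induced_tpm = 40,
                                              basal_tpm = 2),
                                   noise_cv = 0, seed = 1L) {
  if (any(levels < 0)) stop("expression levels must be non-negative")
  if (!(levels[["high_tpm"]] > levels[["low_tpm"]]))
    stop("high_tpm must exceed low_tpm")
  known <- c("Group1", "Group2", "Group3", "Group4", "ungrouped")
  if (!all(names(n_per_group) %in% known))
    stop("groups must be among: ", paste(known, collapse = ", "))
  labels <- rep(names(n_per_group), times = n_per_group)
  n <- length(labels)
  cols <- c(stages, "Control", treatments)
  roles <- stats::setNames(c(rep("stage", length(stages)), "control",
                             rep("treatment", length(treatments))), cols)
  if (n == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(cols),
                dimnames = list(NULL, cols))
    attr(m, "col_roles") <- roles
    return(list(values = m, roles = roles,
                truth = stats::setNames(character(0), character(0))))
  }
  mid <- sqrt(levels[["high_tpm"]] * levels[["low_tpm"]]) +
    levels[["basal_tpm"]]
  base_row <- function(lab) {
    st <- switch(lab,
                 Group1 = levels[["high_tpm"]],
                 Group2 = levels[["low_tpm"]],
                 mid)
    ctrl <- switch(lab,
                   Group3 = levels[["basal_tpm"]],
                   Group4 = levels[["induced_tpm"]],
                   st)
    tr <- switch(lab,
                 Group3 = levels[["induced_tpm"]],
                 Group4 = levels[["basal_tpm"]],
                 ctrl)
    c(rep(st, length(stages)), ctrl, rep(tr, length(treatments)))
  }
  with_seed(seed, {
    m <- t(vapply(labels, base_row, numeric(length(cols))))
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      m <- m * matrix(stats::rlnorm(length(m), meanlog = -sdlog^2 / 2,
                                    sdlog = sdlog), nrow = n)
    }
    genes <- sprintf("gene_%04d", seq_len(n))
    dimnames(m) <- list(genes, cols)
    attr(m, "col_roles") <- roles
    list(values = m, roles = roles,
         truth = stats::setNames(labels, genes))
  })
}

#' Generate a qPCR CT table with planted fold changes
#'
#' Reference-gene CTs are constant; under each non-control condition the
#' target CT is lowered by exactly `log2(fold)` cycles relative to its
#' control CT, so [ddct_fold_change()] recovers the planted fold exactly.
#'
#' @param genes Character vector of target gene ids.
#' @param conditions Non-control condition labels.
#' @param true_fold Matrix (genes x conditions) or single number of positive
#'   fold changes.
#' @param ct_reference Constant CT of the reference gene.
#' @param ct_target_control Base CT of each target under the control.
#' @param seed Integer seed (used only to draw per-gene base CTs when
#'   `ct_target_control` is `NULL`).
#' @return List with `table` (data frame `gene`, `condition`, `ct_target`,
#'   `ct_reference`; the control condition is labeled `"Control"`) and
#'   `truth` (fold-change matrix).
#' @export
make_qpcr_table <- function(genes, conditions, true_fold,
                            ct_reference = 20, ct_target_control = 25,
                            seed = 1L) {
  if (is.null(dim(true_fold)))
    true_fold <- matrix(true_fold, nrow = length(genes),
                        ncol = length(conditions),
                        dimnames = list(genes, conditions))
  if (any(true_fold <= 0)) stop("fold changes must be positive")
  with_seed(seed, {
    base <- if (is.null(ct_target_control))
      stats::setNames(stats::runif(length(genes), 22, 30), genes)
    else stats::setNames(rep(ct_target_control, length(genes)), genes)
    rows <- list()
    for (g in genes) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = "Control", ct_target = base[[g]],
        ct_reference = ct_reference)
      for (cond in conditions) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, condition = cond,
          ct_target = base[[g]] - log2(true_fold[g, cond]),
          ct_reference = ct_reference)
      }
    }
    list(table = do.call(rbind, rows), truth = true_fold)
  })
}

#' Generate synthetic wheat-style gene models
#'
#' Distributes genes over homoeologous chromosome groups according to
#' planted group sizes, cycling the A/B/D subgenomes within each group.
#'
#' @param group_sizes Named counts per homoeologous group (`"1"`..`"7"`,
#'   `"Un"`).
#' @param seed Integer seed.
#' @return Gene-model data frame (0-based half-open coordinates).
#' @export
make_gene_models <- function(group_sizes = c(`1` = 19, `2` = 21, `3` = 35,
                                             `4` = 20, `5` = 16, `6` = 12,
                                             `7` = 13, Un = 2), seed = 1L) {
  with_seed(seed, {
    rows <- list(); k <- 0L
    for (g in names(group_sizes)) {
      for (j in seq_len(group_sizes[[g]])) {
        k <- k + 1L
        chrom <- if (g == "Un") "Un"
                 else paste0(g, c("A", "B", "D")[(j - 1L) %% 3L + 1L])
        start <- sample.int(5e7, 1L)
        rows[[k]] <- data.frame(gene_id = sprintf("g%04d", k),
                                chromosome = chrom, start = start,
                                end = start + sample(500:5000, 1L),
                                strand = sample(c("+", "-"), 1L))
      }
    }
    do.call(rbind, rows)
  })
}
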