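# Expression-matrix processing: constitutive (developmental) and
# stress-responsive group assignment, row scaling, hierarchical ordering
# for heatmaps, and qPCR 2^-ddCt fold changes.

expr_roles <- function(m, roles = NULL) {
  if (is.null(roles)) roles <- attr(m, "col_roles")
  if (is.null(roles))
    stop("expression matrix must carry column roles (attribute 'col_roles' ",
         "or the roles argument)")
  if (!all(colnames(m) %in% names(roles)))
    stop("every column must have a role tag")
  roles[colnames(m)]
}

#' Assign constitutive expression groups from developmental stages
#'
#' Group 1: TPM at or above `high_tpm` in at least a fraction `fraction` of
#' stage columns ("constitutively high in nearly all stages"); Group 2:
#' TPM below `low_tpm` in at least that fraction (and not Group 1);
#' otherwise ungrouped. The thresholds quantify "high/low abundance in
#' nearly all stages" and are recorded in the output.
#'
#' @param m TPM matrix (genes x conditions) with column roles.
#' @param high_tpm,low_tpm TPM thresholds (defaults 10 and 1).
#' @param fraction Required fraction of stage columns (default 0.8).
#' @param roles Optional named role vector overriding `attr(m, "col_roles")`.
#' @return List with `groups` (named character: `Group1`, `Group2` or
#'   `ungrouped`) and `parameters`.
#' @export
assign_development_groups <- function(m, high_tpm = 10, low_tpm = 1,
                                      fraction = 0.8, roles = NULL) {
  stopifnot(high_tpm > low_tpm, low_tpm >= 0, fraction > 0, fraction <= 1)
  roles <- expr_roles(m, roles)
  stage_cols <- names(roles)[roles == "stage"]
  if (!length(stage_cols)) stop("no stage columns in the matrix")
  sm <- m[, stage_cols, drop = FALSE]
  hi <- rowMeans(sm >= high_tpm) >= fraction
  lo <- rowMeans(sm < low_tpm) >= fraction
  g <- ifelse(hi, "Group1", ifelse(lo, "Group2", "ungrouped"))
  list(groups = stats::setNames(g, rownames(m)),
       parameters = list(high_tpm = high_tpm, low_tpm = low_tpm,
                         fraction = fraction, n_stages = length(stage_cols)))
}

#' Assign stress-responsive expression groups
#'
#' Group 3 (induced): treatment/control TPM ratio at or above
#' `induced_ratio` in at least a fraction `fraction` of treatment columns;
#' Group 4 (repressed): ratio at or below `1/induced_ratio` in at least
#' that fraction. A pseudocount is added to both numerator and denominator
#' so silent genes do not divide by zero. A gene meeting both definitions
#' is left ungrouped with a warning.
#'
#' @param m TPM matrix with column roles (one `control` column required).
#' @param induced_ratio Fold-change threshold (> 1, default 2).
#' @param fraction Required fraction of treatment columns (default 0.5).
#' @param pseudocount Added to both sides of the ratio (default 0.5).
#' @param roles Optional role vector.
#' @return List with `groups` (named character: `Group3`, `Group4` or
#'   `ungrouped`) and `parameters`.
#' @export
assign_stress_groups <- function(m, induced_ratio = 2, fraction = 0.5,
                                 pseudocount = 0.5, roles = NULL) {
  stopifnot(induced_ratio > 1, fraction > 0, fraction <= 1)
  roles <- expr_roles(m, roles)
  ctrl <- names(roles)[roles == "control"]
  if (length(ctrl) != 1L) stop("exactly one control column is required")
  treat <- names(roles)[roles == "treatment"]
  if (!length(treat)) stop("no treatment columns in the matrix")
  ratio <- (m[, treat, drop = FALSE] + pseudocount) /
    (m[, ctrl] + pseudocount)
  up <- rowMeans(ratio >= induced_ratio) >= fraction
  down <- rowMeans(ratio <= 1 / induced_ratio) >= fraction
  both <- up & down
  if (any(both)) {
    warning("gene(s) meeting both induced and repressed definitions left ",
            "ungrouped: ", paste(rownames(m)[both], collapse = ", "))
    up[both] <- down[both] <- FALSE
  }
  g <- ifelse(up, "Group3", ifelse(down, "Group4", "ungrouped"))
  list(groups = stats::setNames(g, rownames(m)),
       parameters = list(induced_ratio = induced_ratio, fraction = fraction,
                         pseudocount = pseudocount,
                         control = ctrl, n_treatments = length(treat)))
}

#' Row-wise z-scaling of log-transformed TPM
#'
#' Each row is transformed to `log2(TPM + 1)` and centered/scaled to mean 0
#' and standard deviation 1. Constant rows become all-zero and are flagged
#' in the `constant_rows` attribute.
#'
#' @param m TPM matrix.
#' @return Scaled matrix with attribute `constant_rows`.
#' @export
zscore_rows <- function(m) {
  lg <- log2(m + 1)
  mu <- rowMeans(lg)
  sd <- apply(lg, 1, stats::sd)
  const <- sd == 0 | is.na(sd)
  sd[const] <- 1
  out <- (lg - mu) / sd
  out[const, ] <- 0
  attr(out, "constant_rows") <- rownames(m)[const]
  out
}

#' Hierarchical ordering of expression profiles
#'
#' Average-linkage agglomerative clustering on `1 - Pearson correlation`
#' of the row-scaled `log2(TPM + 1)` profiles, the usual heatmap ordering.
#' Rows with undefined correlation (constant profiles) are placed at
#' distance 1 from everything and flagged.
#'
#' @param m TPM matrix with at least 2 rows.
#' @return List with `order` (gene ids in dendrogram leaf order), `hclust`
#'   (the [stats::hclust] object), `newick` (the dendrogram serialized via
#'   [ape::write.tree()]) and `flagged` (constant rows).
#' @export
hierarchical_order <- function(m) {
  stopifnot(nrow(m) >= 2L)
  z <- zscore_rows(m)
  cc <- suppressWarnings(stats::cor(t(z)))
  d <- 1 - cc
  flagged <- attr(z, "constant_rows")
  bad <- is.na(d)
  d[bad] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  list(order = rownames(m)[hc$order], hclust = hc,
       newick = ape::write.tree(phy), flagged = flagged)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (CT_target,cond - CT_ref,cond) - (CT_target,control -
#' CT_ref,control)`; the fold change is `2^-ddCt`. The control condition
#' maps to fold 1 exactly, and the result is invariant to any constant
#' offset added to all CT values.
#'
#' @param q Data frame with columns `gene`, `condition`, `ct_target`,
#'   `ct_reference`.
#' @param control Label of the control condition (default `"Control"`).
#' @return Data frame `gene`, `condition`, `ddct`, `fold`.
#' @export
ddct_fold_change <- function(q, control = "Control") {
  need <- c("gene", "condition", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(q)))
  if (any(!is.finite(q$ct_target)) || any(!is.finite(q$ct_reference))) {
    i <- which(!is.finite(q$ct_target) | !is.finite(q$ct_reference))[1]
    stop("missing CT value for gene ", q$gene[i], ", condition ",
         q$condition[i])
  }
  out <- list()
  for (g in unique(q$gene)) {
    sub <- q[q$gene == g, , drop = FALSE]
    ctrl <- sub[sub$condition == control, , drop = FALSE]
    if (nrow(ctrl) != 1L)
      stop("gene ", g, " must have exactly one control row")
    dct_ctrl <- ctrl$ct_target - ctrl$ct_reference
    ddct <- (sub$ct_target - sub$ct_reference) - dct_ctrl
    out[[length(out) + 1L]] <- data.frame(gene = g,
                                          condition = sub$condition,
                                          ddct = ddct, fold = 2^(-ddct))
  }
  do.call(rbind, out)
}

#' Write / read a TPM matrix with column-role tags as TSV
#'
#' The first line is a `#roles` comment mapping each column to its role
#' (`stage`, `control`, `treatment`); the table proper follows with a
#' header row.
#'
#' @param m Matrix with `col_roles` attribute.
#' @param path File path.
#' @return `write_expression_matrix` returns `path` invisibly;
#'   `read_expression_matrix` returns the matrix with roles restored.
#' @export
write_expression_matrix <- function(m, path) {
  roles <- expr_roles(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#roles\t",
                    paste(colnames(m), roles, sep = "=", collapse = "\t")),
             con)
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#roles"))
    stop("missing #roles header line")
  pairs <- strsplit(strsplit(lines[1], "\t")[[1]][-1], "=", fixed = TRUE)
  roles <- stats::setNames(vapply(pairs, `[`, character(1), 2L),
                           vapply(pairs, `[`, character(1), 1L))
  tab <- utils::read.delim(textConnection(lines[-1]), check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  attr(m, "col_roles") <- roles
  m
}
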