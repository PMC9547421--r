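# The rule engine at the heart of the package: RING-type zinc-finger domains
# are located by matching an ordered set of metal-ligand "slots" (allowed
# residues at eight -- nine for the accessory IBR domain -- zinc-coordinating
# positions) separated by bounded spacer ranges, then classified into
# subtypes by which rule matched.

#' Construct a ligand rule
#'
#' A rule is an ordered list of ligand slots. Each slot allows a set of
#' residues; consecutive slots are separated by an inclusive spacer range
#' (number of intervening residues). The last slot carries no spacer.
#'
#' @param name Subtype label (unique within a table).
#' @param priority Integer; lower values are tried first by [scan_all()].
#' @param allowed List of character vectors, one per ligand slot.
#' @param spacers List of length `length(allowed) - 1` of `c(min, max)`
#'   integer ranges.
#' @param accessory Logical; accessory domains (IBR) never compete with core
#'   RING rules for a protein's subtype label.
#' @return An object of class `ligand_rule`.
#' @export
ligand_rule <- function(name, priority, allowed, spacers, accessory = FALSE) {
  stopifnot(length(allowed) >= 2L, length(spacers) == length(allowed) - 1L)
  for (a in allowed) {
    if (!length(a) || !all(a %in% AA_STANDARD))
      stop("rule '", name, "': allowed sets must be non-empty standard residues")
  }
  for (sp in spacers) {
    if (length(sp) != 2L || sp[1] < 0 || sp[1] > sp[2])
      stop("rule '", name, "': spacer ranges must satisfy 0 <= min <= max")
  }
  structure(list(name = name, priority = as.integer(priority),
                 allowed = lapply(allowed, as.character),
                 spacers = lapply(spacers, as.integer),
                 accessory = isTRUE(accessory)),
            class = "ligand_rule")
}

# Generic RING consensus spacers:
# C-X2-C-X(9-39)-C-X(1-3)-H-X(2-3)-C/H-X2-C-X(4-48)-C-X2-C
GENERIC_RING_SPACERS <- list(c(2, 2), c(9, 39), c(1, 3), c(2, 3),
                             c(2, 2), c(4, 48), c(2, 2))

#' Default RING subtype rule table
#'
#' Returns, in priority order:
#' \describe{
#'   \item{RING-M}{`M-X2-R-X14-C-X1-H-X2-C-X2-C-X10-C-X2-C` -- the modified
#'     subtype with Met and Arg at metal-ligand positions 1 and 2 and fixed
#'     spacers; positions 3 and 4 carry conventional RING-HC-type ligands.}
#'   \item{RING-D}{generic consensus spacers with Asp replacing the Cys/His
#'     at ligand slot 5. The literature does not fix which ligand carries the
#'     Asp substitution; slot 5 is this package's configurable default.}
#'   \item{RING-H2}{C3H2C3: His at ligand slots 4 and 5, generic spacers.}
#'   \item{RING-HC}{C3HC4: His at slot 4, Cys at slot 5, generic spacers.
#'     [split_hc()] refines RING-HC hits into HCa/HCb.}
#'   \item{IBR}{accessory 9-ligand C6HC-type rule
#'     `C-X4-C-X(14-30)-C-X(1-4)-C-X4-C-X2-C-X4-H-X4-C`; reported alongside,
#'     never instead of, a core RING hit.}
#' }
#'
#' @return A list of [ligand_rule()] objects.
#' @export
default_rule_table <- function() {
  C <- "C"; H <- "H"
  list(
    ligand_rule("RING-M", 1L,
                allowed = list("M", "R", C, H, C, C, C, C),
                spacers = list(c(2, 2), c(14, 14), c(1, 1), c(2, 2),
                               c(2, 2), c(10, 10), c(2, 2))),
    ligand_rule("RING-D", 2L,
                allowed = list(C, C, C, H, "D", C, C, C),
                spacers = GENERIC_RING_SPACERS),
    ligand_rule("RING-H2", 3L,
                allowed = list(C, C, C, H, H, C, C, C),
                spacers = GENERIC_RING_SPACERS),
    ligand_rule("RING-HC", 4L,
                allowed = list(C, C, C, H, C, C, C, C),
                spacers = GENERIC_RING_SPACERS),
    ligand_rule("IBR", 100L,
                allowed = list(C, C, C, C, C, C, C, H, C),
                spacers = list(c(4, 4), c(14, 30), c(1, 4), c(4, 4),
                               c(2, 2), c(4, 4), c(4, 4), c(4, 4)),
                accessory = TRUE)
  )
}

#' Read or write a rule table as JSON
#'
#' The JSON format is a list of objects
#' `{name, priority, accessory, slots: [{allowed, spacer}, ...]}` where
#' `allowed` is a string of residue letters and `spacer` is a two-element
#' inclusive range (absent on the last slot).
#'
#' @param path JSON file path.
#' @return For `read_rule_table`, a list of [ligand_rule()] objects.
#' @export
read_rule_table <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- lapply(raw, function(r) {
    slots <- r$slots
    allowed <- lapply(slots, function(s) seq_chars(s$allowed))
    spacers <- lapply(slots[-length(slots)],
                      function(s) as.integer(unlist(s$spacer)))
    ligand_rule(r$name, r$priority, allowed, spacers,
                accessory = isTRUE(r$accessory))
  })
  names_ <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(names_)) stop("duplicate rule name in table")
  prios <- vapply(rules, `[[`, integer(1), "priority")
  if (anyDuplicated(prios)) stop("duplicate rule priority in table")
  rules[order(prios)]
}

#' @rdname read_rule_table
#' @param rules A list of [ligand_rule()] objects.
#' @export
write_rule_table <- function(rules, path) {
  out <- lapply(rules, function(r) {
    n <- length(r$allowed)
    slots <- lapply(seq_len(n), function(i) {
      s <- list(allowed = paste(r$allowed[[i]], collapse = ""))
      if (i < n) s$spacer <- r$spacers[[i]]
      s
    })
    list(name = r$name, priority = r$priority, accessory = r$accessory,
         slots = slots)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Depth-first search for the lexicographically smallest spacer vector
# starting from ligand-slot `slot` at 0-based position `pos`. Spacer values
# are tried in increasing order, so the first complete assignment found is
# the lexicographic minimum.
.scan_dfs <- function(ch, rule, slot, pos, positions) {
  n <- length(rule$allowed)
  if (slot == n) return(positions)
  rng <- rule$spacers[[slot]]
  for (sp in rng[1]:rng[2]) {
    nxt <- pos + sp + 1L
    if (nxt > length(ch)) break
    if (ch[nxt] %in% rule$allowed[[slot + 1L]]) {
      res <- .scan_dfs(ch, rule, slot + 1L, nxt, c(positions, nxt))
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

#' Scan a protein sequence with one ligand rule
#'
#' Candidate ligand assignments are enumerated left to right. For each
#' position whose residue can serve as ligand 1, at most one hit is kept:
#' the assignment with the lexicographically smallest spacer vector
#' (deterministic tie-break). Hits anchored at different first-ligand
#' positions are all reported, even when they overlap. `X` never matches a
#' ligand slot.
#'
#' @param seq Amino-acid string.
#' @param rule A [ligand_rule()].
#' @return A list of hits; each hit is a list with elements `start`, `end`
#'   (0-based half-open span from first to last ligand), `positions`
#'   (0-based ligand indices), `residues`, `spacers`, `subtype`,
#'   `rule_name` and `accessory`.
#' @export
scan_rule <- function(seq, rule) {
  if (!nzchar(seq)) return(list())
  ch <- validate_sequence(seq, AA_ALPHABET, "protein sequence")
  starts <- which(ch %in% rule$allowed[[1L]])
  hits <- list()
  for (p in starts) {
    positions <- .scan_dfs(ch, rule, 1L, p, p)
    if (!is.null(positions)) {
      hits[[length(hits) + 1L]] <- list(
        start = positions[1] - 1L,
        end = positions[length(positions)],
        positions = positions - 1L,
        residues = ch[positions],
        spacers = diff(positions) - 1L,
        subtype = rule$name,
        rule_name = rule$name,
        accessory = rule$accessory)
    }
  }
  hits
}

#' Scan a sequence with a full rule table
#'
#' Rules are applied in priority order. When two core rules hit with the
#' same first-ligand position only the higher-priority label survives, so a
#' RING-M domain is labeled RING-M even though its later ligands also
#' satisfy the RING-HC rule. Accessory rules (IBR) never suppress core hits
#' and vice versa.
#'
#' @param seq Amino-acid string.
#' @param rule_table List of [ligand_rule()]s (default [default_rule_table()]).
#' @return List of hits as in [scan_rule()], sorted by start position.
#' @export
scan_all <- function(seq, rule_table = default_rule_table()) {
  stopifnot(length(rule_table) > 0L)
  prios <- vapply(rule_table, `[[`, integer(1), "priority")
  rule_table <- rule_table[order(prios)]
  core_seen <- integer(0)
  out <- list()
  for (rule in rule_table) {
    for (h in scan_rule(seq, rule)) {
      if (!h$accessory) {
        if (h$positions[1] %in% core_seen) next
        core_seen <- c(core_seen, h$positions[1])
      }
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out)) out <- out[order(vapply(out, `[[`, integer(1), "start"))]
  out
}

#' Split a RING-HC hit into RING-HCa / RING-HCb
#'
#' The HCa/HCb distinction is not fixed by a published consensus; this
#' package implements it as a configurable spacer threshold. By default the
#' discriminating region is spacer 6 (0-based `spacer_index = 5`, the
#' variable `X(4-48)` stretch between ligands 6 and 7): HCa iff that spacer
#' is `>= threshold`.
#'
#' @param hit A hit labeled `RING-HC`.
#' @param criterion List with `spacer_index` (0-based, in 0..6) and
#'   `threshold` (integer).
#' @return `"RING-HCa"` or `"RING-HCb"`.
#' @export
split_hc <- function(hit, criterion = list(spacer_index = 5L, threshold = 8L)) {
  if (!identical(hit$rule_name, "RING-HC"))
    stop("split_hc applies only to RING-HC hits, got ", hit$rule_name)
  idx <- criterion$spacer_index
  if (is.null(idx) || idx < 0L || idx > 6L)
    stop("criterion$spacer_index must lie in 0..6")
  if (hit$spacers[idx + 1L] >= criterion$threshold) "RING-HCa" else "RING-HCb"
}

#' Classify a set of proteins and produce the subtype census
#'
#' Each protein is assigned one representative core domain -- the
#' highest-priority, then leftmost hit -- mirroring a one-domain-per-protein
#' family census. Proteins carrying several core domains are additionally
#' listed in a multi-domain report; proteins with no hit are labeled
#' `"unclassified"` and excluded from the census total.
#'
#' @param records Protein data frame (columns `id`, `sequence`).
#' @param rule_table Rule table (default [default_rule_table()]).
#' @param hc_criterion Criterion passed to [split_hc()].
#' @return An object of class `ring_classification`: list with
#'   `assignments` (per-protein data frame), `census` (a `subtype_census`),
#'   `multi_domain` (proteins with 2+ core domains), `hits` (all hits,
#'   including accessory ones, per protein) and `hc_criterion`.
#' @export
classify_proteome <- function(records, rule_table = default_rule_table(),
                              hc_criterion = list(spacer_index = 5L,
                                                  threshold = 8L)) {
  prios <- vapply(rule_table, `[[`, integer(1), "priority")
  prio_of <- stats::setNames(prios, vapply(rule_table, `[[`, character(1),
                                           "name"))
  n <- nrow(records)
  subtype <- character(n); start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n); n_core <- integer(n)
  all_hits <- vector("list", n)
  names(all_hits) <- records$id
  for (i in seq_len(n)) {
    hits <- scan_all(records$sequence[i], rule_table)
    all_hits[[i]] <- hits
    core <- Filter(function(h) !h$accessory, hits)
    n_core[i] <- length(core)
    if (!length(core)) {
      subtype[i] <- "unclassified"
      next
    }
    ord <- order(vapply(core, function(h) prio_of[[h$rule_name]], integer(1)),
                 vapply(core, `[[`, integer(1), "start"))
    rep_hit <- core[[ord[1]]]
    lab <- rep_hit$subtype
    if (identical(lab, "RING-HC")) lab <- split_hc(rep_hit, hc_criterion)
    subtype[i] <- lab
    start[i] <- rep_hit$start
    end[i] <- rep_hit$end
  }
  assignments <- data.frame(protein_id = records$id, subtype = subtype,
                            start = start, end = end, n_core_domains = n_core)
  classified <- assignments[assignments$subtype != "unclassified", ,
                            drop = FALSE]
  counts <- table(classified$subtype)
  census <- subtype_census(stats::setNames(as.integer(counts), names(counts)))
  multi <- assignments[assignments$n_core_domains >= 2L,
                       c("protein_id", "subtype", "n_core_domains")]
  structure(list(assignments = assignments, census = census,
                 multi_domain = multi, hits = all_hits,
                 hc_criterion = hc_criterion),
            class = "ring_classification")
}

#' Subtype census with percentages
#'
#' @param counts Named integer vector of per-subtype counts.
#' @param denominator Denominator for percentages; defaults to the sum of
#'   counts and is recorded in the object.
#' @return Object of class `subtype_census` with `counts`, `percentages`
#'   (one-decimal, half-up), `total` and `denominator`.
#' @export
subtype_census <- function(counts, denominator = sum(counts)) {
  total <- sum(counts)
  pct <- if (denominator > 0)
    vapply(counts, census_percentage, numeric(1), denominator = denominator)
  else stats::setNames(numeric(length(counts)), names(counts))
  structure(list(counts = counts, percentages = pct, total = total,
                 denominator = denominator), class = "subtype_census")
}

#' @export
print.subtype_census <- function(x, ...) {
  cat("Subtype census (", x$total, " classified, denominator ",
      x$denominator, ")\n", sep = "")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %4d  (%.1f%%)\n", nm, x$counts[[nm]],
                x$percentages[[nm]]))
  invisible(x)
}

#' @export
print.ring_classification <- function(x, ...) {
  print(x$census)
  cat(sum(x$assignments$subtype == "unclassified"), "unclassified;",
      nrow(x$multi_domain), "proteins with 2+ core domains\n")
  invisible(x)
}

#' Check that a hit satisfies its rule's constraints
#'
#' Label-soundness assertion: ligand residues belong to the allowed sets and
#' spacers lie in their ranges.
#'
#' @param hit A hit from [scan_rule()].
#' @param rule The [ligand_rule()] it was produced by.
#' @return `TRUE` (invisibly) or an error.
#' @export
assert_hit_sound <- function(hit, rule) {
  stopifnot(length(hit$positions) == length(rule$allowed))
  for (i in seq_along(rule$allowed)) {
    if (!(hit$residues[i] %in% rule$allowed[[i]]))
      stop("ligand ", i, " residue ", hit$residues[i], " not allowed")
  }
  for (i in seq_along(rule$spacers)) {
    sp <- hit$spacers[i]
    if (sp < rule$spacers[[i]][1] || sp > rule$spacers[[i]][2])
      stop("spacer ", i, " value ", sp, " out of range")
  }
  if (any(diff(hit$positions) <= 0)) stop("ligand positions not increasing")
  invisible(TRUE)
}
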