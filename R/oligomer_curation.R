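#' Collect oligomeric evidence for a nominally monomeric gene
#'
#' Scans the deduplicated pseudo-structures for non-monomeric stoichiometries
#' containing the gene.  Monomeric model sources (I-TASSER, AlphaFold)
#' cannot witness oligomerization, so only PDB and SWISS observations are
#' collected; SWISS observations failing the QC gate are removed from
#' consideration.
#'
#' @param gene_id gene to examine.
#' @param pss list of scored, deduplicated `pseudo_structure`s.
#' @param qc named list, structure_id -> result of [qc_model()] (used for
#'   SWISS observations; missing entries fail).
#' @return An `oligomeric_evidence` object: `gene_id` plus an
#'   `observations` data frame (structure_id, source, signature, quality,
#'   heteromeric).
#' @export
collect_evidence <- function(gene_id, pss, qc = list()) {
  rows <- list()
  for (p in pss) {
    st <- p$gene_stoichiometry
    if (!gene_id %in% names(st)) next
    if (sum(st) < 2L) next                      # monomeric instance
    if (!p$source %in% c("PDB", "SWISS")) next
    if (p$source == "SWISS") {
      q <- qc[[p$structure_id]]
      if (is.null(q) || !isTRUE(q$pass)) next   # failing evidence removed
    }
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = p$structure_id, source = p$source,
      signature = p$signature, quality = p$quality,
      heteromeric = length(st) > 1L, stringsAsFactors = FALSE)
  }
  obs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure_id = character(), source = character(),
               signature = character(), quality = numeric(),
               heteromeric = logical(), stringsAsFactors = FALSE)
  obs <- obs[order(obs$structure_id, obs$signature), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(gene_id = gene_id, observations = obs),
            class = "oligomeric_evidence")
}

#' Classify structural oligomerization evidence into curation cases
#'
#' Decision table for structure-guided reannotation of a monomeric gene:
#' \describe{
#'   \item{Case I}{PDB and SWISS both witness the same single homomeric
#'     stoichiometry -> automatic update.}
#'   \item{Case II}{exactly one passing SWISS observation, homomeric, and no
#'     PDB homomeric evidence -> automatic update.}
#'   \item{Case III}{homomeric evidence involving SWISS that is conflicting
#'     (several distinct stoichiometries) or ambiguous (several SWISS
#'     models) -> manual review.}
#'   \item{Case IV}{homomeric evidence only from the PDB -> manual review.}
#'   \item{Case V}{heteromeric evidence only -> manual review.}
#'   \item{NONE}{no oligomeric evidence -> no change.}
#' }
#' The predicates are mutually exclusive and exhaustive, and automatic
#' updates fire only for Cases I and II.
#'
#' @param ev an `oligomeric_evidence` object.
#' @return A `curation_decision`: list with `gene_id`, `case`, `action`
#'   (`AUTO_UPDATE` / `MANUAL_REVIEW` / `NO_CHANGE`), and
#'   `new_stoichiometry` (named integer, only for automatic updates).
#' @export
classify_case <- function(ev) {
  obs <- ev$observations
  decision <- function(case, action, st = NULL)
    structure(list(gene_id = ev$gene_id, case = case, action = action,
                   new_stoichiometry = st,
                   n_observations = nrow(obs)),
              class = "curation_decision")
  if (nrow(obs) == 0) return(decision("NONE", "NO_CHANGE"))
  homo <- obs[!obs$heteromeric, , drop = FALSE]
  if (nrow(homo) == 0) return(decision("V", "MANUAL_REVIEW"))
  sigs <- unique(homo$signature)
  src <- unique(homo$source)
  if ("SWISS" %in% src && "PDB" %in% src) {
    if (length(sigs) == 1L)
      return(decision("I", "AUTO_UPDATE", parse_stoichiometry(sigs)))
    return(decision("III", "MANUAL_REVIEW"))
  }
  if (identical(src, "SWISS")) {
    if (nrow(homo) == 1L)
      return(decision("II", "AUTO_UPDATE", parse_stoichiometry(sigs)))
    return(decision("III", "MANUAL_REVIEW"))
  }
  decision("IV", "MANUAL_REVIEW")
}

#' @export
print.curation_decision <- function(x, ...) {
  cat("<curation_decision> ", x$gene_id, ": Case ", x$case, " -> ", x$action,
      if (!is.null(x$new_stoichiometry))
        paste0(" (", stoich_signature(x$new_stoichiometry), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Apply curation decisions (and manual resolutions) to complex targets
#'
#' Automatic updates replace the gene's monomer target stoichiometry with
#' the structurally supported one; manual-review genes are resolved from the
#' supplied table when present and reported otherwise.  Reannotated targets
#' get provenance `REANNOTATED`.
#'
#' @param targets list of [complex_target()]s (the gene's monomer target is
#'   the one whose stoichiometry is exactly `{gene: 1}`).
#' @param decisions list of `curation_decision`s.
#' @param manual_table optional data frame (or TSV path) with columns
#'   `gene_id`, `new_stoichiometry` (e.g. `"g:4"` or `"g:1,h:1"`),
#'   supplying resolutions for manual-review genes.
#' @param registry a [gene_registry()]; manual resolutions referencing
#'   unknown genes are errors.
#' @return List with `targets` (updated list) and `report` (data frame:
#'   gene, case, action, resolution).
#' @export
apply_curation <- function(targets, decisions, manual_table = NULL,
                           registry = NULL) {
  if (is.character(manual_table))
    manual_table <- utils::read.delim(manual_table, stringsAsFactors = FALSE)
  manual <- list()
  if (!is.null(manual_table) && nrow(manual_table)) {
    for (i in seq_len(nrow(manual_table))) {
      st <- parse_stoichiometry(manual_table$new_stoichiometry[i])
      if (!is.null(registry)) {
        unknown <- setdiff(names(st), registry$gene_id)
        if (length(unknown))
          stop("manual resolution for ", manual_table$gene_id[i],
               " references unknown gene(s): ",
               paste(unknown, collapse = ", "))
      }
      manual[[manual_table$gene_id[i]]] <- st
    }
  }
  monomer_target_of <- function(g) {
    for (k in seq_along(targets)) {
      st <- targets[[k]]$stoichiometry
      if (length(st) == 1L && names(st) == g && st == 1L) return(k)
    }
    NA_integer_
  }
  report <- list()
  for (d in decisions) {
    resolution <- "unchanged"
    new_st <- NULL
    if (identical(d$action, "AUTO_UPDATE")) {
      new_st <- d$new_stoichiometry
      resolution <- "auto"
    } else if (identical(d$action, "MANUAL_REVIEW") &&
               !is.null(manual[[d$gene_id]])) {
      new_st <- manual[[d$gene_id]]
      resolution <- "manual"
    }
    if (!is.null(new_st)) {
      k <- monomer_target_of(d$gene_id)
      if (is.na(k)) {
        resolution <- "no_monomer_target"
      } else {
        targets[[k]] <- complex_target(targets[[k]]$complex_id, new_st,
                                       "REANNOTATED")
      }
    }
    report[[length(report) + 1L]] <- data.frame(
      gene_id = d$gene_id, case = d$case, action = d$action,
      resolution = resolution,
      new_stoichiometry = if (is.null(new_st)) NA_character_ else
        stoich_signature(new_st),
      stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(gene_id = character(), case = character(), action = character(),
               resolution = character(), new_stoichiometry = character(),
               stringsAsFactors = FALSE)
  list(targets = targets, report = report)
}
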