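#' Subcellular compartment identifiers
#'
#' Residue-level compartment vocabulary for a gram-negative cell with two
#' membranes.  1 extracellular; 2 extracellular bulb (outer membrane, OM);
#' 3 embedded OM; 4 periplasmic bulb (OM); 5 OM-associated periplasmic;
#' 6 periplasm; 7 inner-membrane(IM)-associated periplasmic; 8 periplasmic
#' bulb (IM); 9 embedded IM; 10 cytoplasmic bulb (IM); 11 IM-associated
#' cytoplasmic; 12 cytoplasm; 13-14 unknown-orientation bulbs (OM); 15
#' membrane-associated, unresolved; 16-17 unknown-orientation bulbs (IM);
#' 18 membrane-annotated without a viable embedded region; 19 unassigned.
#' @export
COMPARTMENTS <- stats::setNames(1:19, c(
  "extracellular", "extracellular_bulb_OM", "embedded_OM",
  "periplasmic_bulb_OM", "OM_associated_periplasmic", "periplasm",
  "IM_associated_periplasmic", "periplasmic_bulb_IM", "embedded_IM",
  "cytoplasmic_bulb_IM", "IM_associated_cytoplasmic", "cytoplasm",
  "unknown_bulb_OM_side1", "unknown_bulb_OM_side2",
  "membrane_associated_unresolved", "unknown_bulb_IM_side1",
  "unknown_bulb_IM_side2", "membrane_no_viable_slab", "unassigned"))

MEMBRANE_KEYWORDS <- list(
  go = c("membrane", "transport", "abc", "wall", "periplasm"),
  ecocyc = c("membrane", "periplas", "transport", "secretion",
             "extracellular", "wall"),
  gem = c("membrane", "transport", "abc", "wall", "periplasm", "envelope",
          "murein"))

any_keyword <- function(text, keywords) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(FALSE)
  any(vapply(keywords, function(k)
    grepl(k, text, ignore.case = TRUE, fixed = FALSE), logical(1)))
}

#' Is a gene a potential membrane gene?
#'
#' A gene is flagged when any source's keyword rule fires: UniProt features
#' of kind `TOPO_DOM` / `TRANSMEM` / `INTRAMEM`; membrane-related keywords
#' in its GO terms, EcoCyc location, or genome-scale-model subsystem
#' (case-insensitive substring match).
#'
#' @param meta single-row gene metadata (columns `gene_id`, `go`, `ecocyc`,
#'   `gem`; missing columns are ignored).
#' @param uniprot_features features table from [parse_uniprot_features()].
#' @return Logical.
#' @export
is_membrane_gene <- function(meta, uniprot_features = NULL) {
  g <- meta$gene_id[1]
  if (!is.null(uniprot_features)) {
    ft <- uniprot_features[uniprot_features$gene_id == g, , drop = FALSE]
    if (any(ft$kind %in% c("TOPO_DOM", "TRANSMEM", "INTRAMEM"))) return(TRUE)
  }
  for (col in c("go", "ecocyc", "gem")) {
    if (col %in% names(meta) &&
        any_keyword(meta[[col]][1], MEMBRANE_KEYWORDS[[col]])) return(TRUE)
  }
  FALSE
}

#' Flag candidate membrane structures
#'
#' A structure is a membrane candidate iff at least one of its subunit
#' genes is a potential membrane gene.
#'
#' @param structure_genes named list: structure id -> character vector of
#'   subunit gene ids.
#' @param meta gene metadata data frame (one row per gene).
#' @param uniprot_features optional features table.
#' @return Character vector of candidate structure ids.
#' @export
flag_membrane_candidates <- function(structure_genes, meta,
                                     uniprot_features = NULL) {
  mem_genes <- meta$gene_id[vapply(seq_len(nrow(meta)), function(i)
    is_membrane_gene(meta[i, , drop = FALSE], uniprot_features), logical(1))]
  ids <- names(structure_genes)[vapply(structure_genes, function(gs)
    any(gs %in% mem_genes), logical(1))]
  sort(ids)
}

# direct total-least-squares plane: centroid + smallest principal direction
tls_plane <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  normal <- sv$v[, 3]
  # canonical sign: positive z component, tie-broken by y then x
  key <- c(normal[3], normal[2], normal[1])
  first <- key[which(abs(key) > 1e-12)[1]]
  if (!is.na(first) && first < 0) normal <- -normal
  d <- as.numeric(points %*% normal) - sum(normal * ctr)
  list(normal = normal, offset = sum(normal * ctr),
       fit_error = sum(d^2), distances = d)
}

#' Fit a membrane leaflet plane to crossing-residue coordinates
#'
#' Total-least-squares plane (centroid plus smallest principal direction)
#' with iterative outlier removal: for groups of more than four points,
#' each point is provisionally removed, the plane refit on the remainder,
#' and the removal with the smallest residual error is accepted; iteration
#' stops when the variance of point-plane distances improves by less than
#' `var_tol` (relative, default 5%) or when the group would shrink to four
#' points.  This absorbs crossing residues from poorly annotated
#' transmembrane spans.
#'
#' @param points numeric matrix (k x 3) of CA (or dummy-atom) coordinates.
#' @param var_tol relative variance-improvement stopping threshold.
#' @return A `membrane_plane`: `normal` (unit vector, canonical sign),
#'   `offset` (plane is `normal . x = offset`), `fit_error` (sum of squared
#'   distances), `support` (points used in the final fit), `n_removed`.
#' @export
fit_membrane_plane <- function(points, var_tol = 0.05) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("plane fit needs at least 3 points")
  fit <- tls_plane(points)
  sv2 <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv2[2] < 1e-9 * max(sv2[1], 1))
    stop("plane fit needs non-collinear points")
  removed <- 0L
  if (nrow(points) > 4) {
    cur_var <- stats::var(fit$distances)
    repeat {
      k <- nrow(points)
      if (k - 1L <= 4L) break
      if (cur_var < 1e-24) break
      fits <- lapply(seq_len(k), function(i)
        tls_plane(points[-i, , drop = FALSE]))
      errs <- vapply(fits, `[[`, numeric(1), "fit_error")
      best <- which.min(errs)
      new_fit <- fits[[best]]
      new_var <- stats::var(new_fit$distances)
      if (cur_var <= 0 || (cur_var - new_var) / cur_var < var_tol) break
      points <- points[-best, , drop = FALSE]
      fit <- new_fit
      cur_var <- new_var
      removed <- removed + 1L
    }
  }
  structure(list(normal = fit$normal, offset = fit$offset,
                 fit_error = fit$fit_error, support = points,
                 n_removed = removed),
            class = "membrane_plane")
}

#' @export
print.membrane_plane <- function(x, ...) {
  cat(sprintf("<membrane_plane> n=(%.3f, %.3f, %.3f) offset=%.2f err=%.3g (%d pts, %d removed)\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset, x$fit_error,
              nrow(x$support), x$n_removed))
  invisible(x)
}

plane_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  cbind(u, v)
}

project_to_plane <- function(points, plane) {
  B <- plane_basis(plane$normal)
  as.matrix(points) %*% B
}

#' Assess a pair of fitted leaflet planes
#'
#' A membrane slab is viable when (i) the acute angle between the two plane
#' normals is strictly below 35 degrees, (ii) the thickness -- the mean
#' unsigned gap between the planes measured along the averaged normal at
#' the embedded CA positions -- lies in the inclusive band 12-45 angstroms,
#' and (iii) the convex-hull areas of the embedded residues projected into
#' both planes are strictly below 10,000 square angstroms.
#'
#' @param p1,p2 `membrane_plane`s.
#' @param embedded_points matrix of embedded CA coordinates.
#' @param source source tag carried through ("UNIPROT", "DEEPTMHMM",
#'   "OPM").
#' @param max_angle,thick_range,max_area viability thresholds.
#' @return A `membrane_assessment`: planes, `angle_deg`, `thickness_A`,
#'   `area_L1`, `area_L2`, `viable`, `reasons`, `source`, plus the averaged
#'   normal and mid-plane offset used downstream for residue splitting.
#' @export
assess_membrane <- function(p1, p2, embedded_points, source = NA_character_,
                            max_angle = 35, thick_range = c(12, 45),
                            max_area = 10000) {
  embedded_points <- as.matrix(embedded_points)
  cosang <- abs(sum(p1$normal * p2$normal))
  angle <- acos(pmin(1, cosang)) * 180 / pi
  n2 <- if (sum(p1$normal * p2$normal) < 0) -p2$normal else p2$normal
  off2 <- if (sum(p1$normal * p2$normal) < 0) -p2$offset else p2$offset
  navg <- p1$normal + n2
  navg <- navg / sqrt(sum(navg^2))
  reasons <- character(0)
  thickness <- NA_real_
  a1 <- a2 <- NA_real_
  if (nrow(embedded_points) >= 1) {
    t1 <- (p1$offset - embedded_points %*% p1$normal) /
      sum(p1$normal * navg)
    t2 <- (off2 - embedded_points %*% n2) / sum(n2 * navg)
    thickness <- mean(abs(t1 - t2))
  }
  if (nrow(embedded_points) >= 3) {
    a1 <- hull_area_2d(project_to_plane(embedded_points, p1))
    a2 <- hull_area_2d(project_to_plane(embedded_points,
                                        list(normal = n2)))
  }
  mid <- mean(c(sum(navg * p1$normal) * p1$offset,
                sum(navg * n2) * off2))
  # mid-plane offset along navg: average of the two plane offsets expressed
  # against the averaged normal at the embedded centroid
  mid <- if (nrow(embedded_points) >= 1) {
    ctr <- colMeans(embedded_points)
    tt1 <- (p1$offset - sum(ctr * p1$normal)) / sum(p1$normal * navg)
    tt2 <- (off2 - sum(ctr * n2)) / sum(n2 * navg)
    sum(navg * ctr) + (tt1 + tt2) / 2
  } else (p1$offset + off2) / 2

  if (!(angle < max_angle)) reasons <- c(reasons, "angle")
  if (is.na(thickness) || thickness < thick_range[1] ||
      thickness > thick_range[2]) reasons <- c(reasons, "thickness")
  if (is.na(a1) || is.na(a2)) reasons <- c(reasons, "area_undefined")
  else if (!(max(a1, a2) < max_area)) reasons <- c(reasons, "area")
  structure(
    list(planes = list(p1, p2), angle_deg = angle, thickness_A = thickness,
         area_L1 = a1, area_L2 = a2, viable = length(reasons) == 0,
         reasons = reasons, source = source, mid_normal = navg,
         mid_offset = mid),
    class = "membrane_assessment")
}

#' @export
print.membrane_assessment <- function(x, ...) {
  cat(sprintf("<membrane_assessment> [%s] angle=%.1f deg thickness=%.1f A areas=(%.0f, %.0f) A^2 -> %s\n",
              x$source, x$angle_deg, x$thickness_A,
              ifelse(is.na(x$area_L1), -1, x$area_L1),
              ifelse(is.na(x$area_L2), -1, x$area_L2),
              if (x$viable) "viable" else
                paste("not viable:", paste(x$reasons, collapse = ","))))
  invisible(x)
}

#' Fit and assess the membrane slab for one crossing set
#'
#' @param set a `membrane_crossing_set`.
#' @param record the `structure_record` supplying CA coordinates.
#' @param ... thresholds passed to [assess_membrane()].
#' @return A `membrane_assessment`, or `NULL` when either leaflet has
#'   fewer than 3 support points.
#' @export
assess_crossing_set <- function(set, record, ...) {
  coords_of <- function(df) {
    idx <- match(paste(df$chain, df$resno),
                 paste(record$atoms$chain, record$atoms$resno))
    as.matrix(record$atoms[idx[!is.na(idx)], c("x", "y", "z")])
  }
  pts <- if (!is.null(set$opm_points))
    list(set$opm_points$L1, set$opm_points$L2)
  else lapply(set$groups, coords_of)
  if (any(vapply(pts, nrow, integer(1)) < 3)) return(NULL)
  p1 <- tryCatch(fit_membrane_plane(pts[[1]]), error = function(e) NULL)
  p2 <- tryCatch(fit_membrane_plane(pts[[2]]), error = function(e) NULL)
  if (is.null(p1) || is.null(p2)) return(NULL)
  emb <- coords_of(set$embedded)
  out <- assess_membrane(p1, p2, emb, source = set$source, ...)
  out$set <- set
  out
}

#' Choose among viable membrane assessments by source deference
#'
#' Structure-based OPM planes are most trusted, then curated UniProt
#' topology, then sequence-only DeepTMHMM predictions.
#'
#' @param assessments list of `membrane_assessment`s (at most one per
#'   source).
#' @return The highest-priority viable assessment, or `NULL` when none is
#'   viable.
#' @export
choose_source <- function(assessments) {
  assessments <- Filter(function(a) !is.null(a) && isTRUE(a$viable),
                        assessments)
  if (length(assessments) == 0) return(NULL)
  pr <- c(OPM = 1, UNIPROT = 2, DEEPTMHMM = 3)
  ranks <- vapply(assessments, function(a) pr[[a$source]], numeric(1))
  assessments[[which.min(ranks)]]
}

# signed distance of every residue to the slab mid-plane
residue_slab_split <- function(record, assessment) {
  a <- record$atoms
  s <- as.matrix(a[, c("x", "y", "z")]) %*% assessment$mid_normal -
    assessment$mid_offset
  half <- assessment$thickness_A / 2
  data.frame(chain = a$chain, resno = a$resno, signed = as.numeric(s),
             region = ifelse(abs(s) <= half, "embedded",
                             ifelse(s > 0, "bulb_pos", "bulb_neg")),
             stringsAsFactors = FALSE)
}

#' Orient a membrane protein's bulbs
#'
#' Residues on either side of the slab ("bulbs") are labeled cytoplasmic,
#' periplasmic or extracellular by maximum agreement with the UniProt
#' topological-domain spans mapped through the gene-chain alignments.  When
#' no UniProt topology exists, a manual orientation table (structure id ->
#' side labels) is consulted; failing both, the orientation is unknown.
#'
#' @param record `structure_record`.
#' @param assessment viable `membrane_assessment`.
#' @param alignments entity -> `chain_gene_alignment` list.
#' @param uniprot_features features table (TOPO_DOM rows used).
#' @param manual_table optional data frame or TSV path with columns
#'   `structure_id`, `side_pos`, `side_neg` (labels from the allowed
#'   vocabulary).
#' @return List with `known`, `side_pos`, `side_neg`, `method`.
#' @export
orient_protein <- function(record, assessment, alignments,
                           uniprot_features = NULL, manual_table = NULL) {
  vocab <- c("cytoplasmic", "periplasmic", "extracellular")
  split <- residue_slab_split(record, assessment)
  if (!is.null(uniprot_features) && nrow(uniprot_features)) {
    topo <- uniprot_features[uniprot_features$kind == "TOPO_DOM", ,
                             drop = FALSE]
    topo$label <- normalize_topo_label(topo$note)
    topo <- topo[!is.na(topo$label), , drop = FALSE]
    if (nrow(topo)) {
      votes <- matrix(0L, nrow = 2, ncol = 3,
                      dimnames = list(c("bulb_pos", "bulb_neg"), vocab))
      for (i in seq_len(nrow(topo))) {
        mp <- map_gene_positions(record, alignments, topo$gene_id[i],
                                 topo$start[i]:topo$end[i])
        if (!nrow(mp)) next
        reg <- split$region[match(paste(mp$chain, mp$resno),
                                  paste(split$chain, split$resno))]
        for (side in c("bulb_pos", "bulb_neg"))
          votes[side, topo$label[i]] <-
            votes[side, topo$label[i]] + sum(reg == side, na.rm = TRUE)
      }
      if (sum(votes) > 0) {
        lab <- function(side) {
          v <- votes[side, ]
          if (sum(v) == 0 || sum(v == max(v)) > 1) NA_character_
          else vocab[which.max(v)]
        }
        sp <- lab("bulb_pos"); sn <- lab("bulb_neg")
        if (!is.na(sp) && !is.na(sn) && sp != sn)
          return(list(known = TRUE, side_pos = sp, side_neg = sn,
                      method = "uniprot"))
        # one resolved side determines the other for a single membrane
        if (!is.na(sp) && is.na(sn))
          return(list(known = TRUE, side_pos = sp,
                      side_neg = opposite_side(sp), method = "uniprot"))
        if (!is.na(sn) && is.na(sp))
          return(list(known = TRUE, side_pos = opposite_side(sn),
                      side_neg = sn, method = "uniprot"))
      }
    }
  }
  if (is.character(manual_table) && length(manual_table) == 1)
    manual_table <- utils::read.delim(manual_table, stringsAsFactors = FALSE)
  if (!is.null(manual_table)) {
    row <- manual_table[manual_table$structure_id == record$structure_id, ,
                        drop = FALSE]
    if (nrow(row) == 1) {
      sp <- tolower(row$side_pos); sn <- tolower(row$side_neg)
      if (!all(c(sp, sn) %in% vocab))
        stop("manual orientation labels must be one of: ",
             paste(vocab, collapse = ", "))
      return(list(known = TRUE, side_pos = sp, side_neg = sn,
                  method = "manual"))
    }
  }
  list(known = FALSE, side_pos = NA_character_, side_neg = NA_character_,
       method = "none")
}

opposite_side <- function(label) {
  # across a single membrane, periplasmic faces either cytoplasmic (IM) or
  # extracellular (OM); the unambiguous complements:
  switch(label,
         cytoplasmic = "periplasmic",
         extracellular = "periplasmic",
         periplasmic = "cytoplasmic")
}

membrane_identity_from_meta <- function(meta_rows) {
  txt <- tolower(paste(unlist(meta_rows[, intersect(c("ecocyc", "go", "gem"),
                                                    names(meta_rows))]),
                       collapse = " "))
  if (grepl("outer membrane", txt)) return("OM")
  if (grepl("inner membrane|plasma membrane|cytoplasmic membrane", txt))
    return("IM")
  NA_character_
}

keyword_groups <- function(meta_rows) {
  txt <- tolower(paste(unlist(meta_rows[, intersect(c("ecocyc", "go", "gem"),
                                                    names(meta_rows))]),
                       collapse = " "))
  g <- character(0)
  if (grepl("cyto", txt)) g <- c(g, "cytoplasm")
  if (grepl("membrane|wall|transport", txt)) g <- c(g, "membrane")
  if (grepl("periplas", txt)) g <- c(g, "periplasm")
  if (grepl("extracellular", txt)) g <- c(g, "extracellular")
  g
}

#' Assign every residue of a structure to a subcellular compartment
#'
#' Total assignment: each residue receives exactly one compartment id from
#' [COMPARTMENTS].  Membrane proteins with a viable slab are split into the
#' embedded region and two bulbs at half-thickness from the mid-plane;
#' oriented bulbs map to compartments 2/4 (outer membrane) or 8/10 (inner
#' membrane) and the slab to 3 or 9.  The membrane identity follows the
#' bulb labels (an extracellular side implies the outer membrane, a
#' cytoplasmic side the inner membrane), falling back to gene-level
#' annotation, and to the unresolved compartment 15 when neither decides.
#' Unoriented membrane proteins land in 13-14 (OM) or 16-17 (IM).
#' Proteins without a viable slab are classified from keyword groups over
#' the combined gene metadata: membrane+cytoplasm -> 11, membrane+periplasm
#' -> 5 (OM) or 7 (IM), membrane alone -> 18, cytoplasm -> 12, periplasm ->
#' 6, extracellular -> 1, nothing (or ambiguous non-membrane combinations)
#' -> 19.
#'
#' @param record `structure_record`.
#' @param meta gene metadata rows for the structure's subunit genes.
#' @param assessment viable `membrane_assessment` or `NULL`.
#' @param orientation result of [orient_protein()] (ignored when
#'   `assessment` is `NULL`).
#' @param membrane_candidate was the structure flagged as a candidate
#'   membrane structure?
#' @return Data frame `chain`, `resno`, `compartment` (integer 1-19)
#'   covering every residue of the record.
#' @export
assign_compartments <- function(record, meta, assessment = NULL,
                                orientation = NULL,
                                membrane_candidate = FALSE) {
  a <- record$atoms
  out <- data.frame(chain = a$chain, resno = a$resno,
                    compartment = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(assessment) && isTRUE(assessment$viable)) {
    split <- residue_slab_split(record, assessment)
    side_label <- c(bulb_pos = NA_character_, bulb_neg = NA_character_)
    oriented <- !is.null(orientation) && isTRUE(orientation$known)
    if (oriented) {
      side_label["bulb_pos"] <- orientation$side_pos
      side_label["bulb_neg"] <- orientation$side_neg
    }
    identity <- NA_character_
    if (oriented) {
      if ("extracellular" %in% side_label) identity <- "OM"
      else if ("cytoplasmic" %in% side_label) identity <- "IM"
    }
    if (is.na(identity)) identity <- membrane_identity_from_meta(meta)
    if (is.na(identity) && !oriented) identity <- "IM"  # default membrane
    if (is.na(identity)) {
      out$compartment <- 15L
      return(out)
    }
    emb_id <- if (identity == "OM") 3L else 9L
    bulb_id <- function(side) {
      lab <- side_label[[side]]
      if (oriented) {
        if (identity == "OM") {
          if (identical(lab, "extracellular")) return(2L)
          if (identical(lab, "periplasmic")) return(4L)
          return(15L)
        } else {
          if (identical(lab, "cytoplasmic")) return(10L)
          if (identical(lab, "periplasmic")) return(8L)
          return(15L)
        }
      }
      if (identity == "OM") {
        if (side == "bulb_pos") 13L else 14L
      } else {
        if (side == "bulb_pos") 16L else 17L
      }
    }
    out$compartment[split$region == "embedded"] <- emb_id
    out$compartment[split$region == "bulb_pos"] <- bulb_id("bulb_pos")
    out$compartment[split$region == "bulb_neg"] <- bulb_id("bulb_neg")
    return(out)
  }
  # no viable slab: keyword classification, whole protein
  groups <- keyword_groups(meta)
  cmpt <- if ("membrane" %in% groups) {
    if ("cytoplasm" %in% groups) 11L
    else if ("periplasm" %in% groups) {
      if (identical(membrane_identity_from_meta(meta), "OM")) 5L else 7L
    } else 18L
  } else if (identical(groups, "cytoplasm")) 12L
  else if (identical(groups, "periplasm")) 6L
  else if (identical(groups, "extracellular")) 1L
  else 19L
  out$compartment <- cmpt
  out
}
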