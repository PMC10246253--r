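#' Volume profile of a protein from its subunit convex hulls
#'
#' The volume of each subunit (chain) is the volume of the convex hull of
#' its atoms (CA fallback), and the protein volume is the *sum* of subunit
#' volumes -- two touching subunits do not share a joint hull.  Degenerate
#' subunits (fewer than four non-coplanar atoms) contribute zero volume and
#' are reported.
#'
#' @param record a `structure_record`.
#' @param complex_id id carried into the profile.
#' @return A `geometric_profile`: `complex_id`, `subunit_volumes` (named by
#'   chain), `total_volume`, `degenerate_chains`, plus `membrane_area` /
#'   `area_by_plane` slots filled by [membrane_footprint()].
#' @export
protein_volume <- function(record, complex_id = record$structure_id) {
  chains <- unique(record$atoms$chain)
  vols <- stats::setNames(numeric(length(chains)), chains)
  degen <- character(0)
  for (ch in chains) {
    h <- convex_hull_3d(ca_coords(record, ch))
    vols[[ch]] <- h$volume
    if (h$degenerate) degen <- c(degen, ch)
  }
  if (length(degen))
    warning("degenerate subunit hull(s) with zero volume: ",
            paste(degen, collapse = ", "))
  structure(
    list(complex_id = complex_id, subunit_volumes = vols,
         total_volume = sum(vols), degenerate_chains = degen,
         membrane_area = NA_real_, area_by_plane = c(NA_real_, NA_real_)),
    class = "geometric_profile")
}

#' @export
print.geometric_profile <- function(x, ...) {
  cat(sprintf("<geometric_profile> %s: %d subunit(s), volume %.1f A^3",
              x$complex_id, length(x$subunit_volumes), x$total_volume))
  if (!is.na(x$membrane_area))
    cat(sprintf(", footprint %.1f A^2", x$membrane_area))
  cat("\n")
  invisible(x)
}

#' Membrane footprint of a protein
#'
#' Projects the convex-hull vertices of every subunit into each fitted
#' leaflet plane and takes the 2-D convex-hull area of each projection.
#' Because a bulb can limit packing, the *larger* of the two areas is the
#' protein's membrane area requirement.  With `embedded_only = TRUE` only
#' residues inside the slab are projected.
#'
#' @param record a `structure_record`.
#' @param assessment a viable `membrane_assessment`.
#' @param profile optional `geometric_profile` to fill in.
#' @param embedded_only project only slab residues instead of whole-protein
#'   hull vertices.
#' @return The updated `geometric_profile` (created if not supplied), with
#'   `area_by_plane` and `membrane_area = max(area_by_plane)`.
#' @export
membrane_footprint <- function(record, assessment, profile = NULL,
                               embedded_only = FALSE) {
  if (is.null(profile)) profile <- protein_volume(record)
  if (is.null(assessment) || !isTRUE(assessment$viable)) {
    profile$membrane_area <- NA_real_
    profile$area_by_plane <- c(NA_real_, NA_real_)
    return(profile)
  }
  if (embedded_only) {
    split <- residue_slab_split(record, assessment)
    keep <- split$region == "embedded"
    pts <- as.matrix(record$atoms[keep, c("x", "y", "z"), drop = FALSE])
  } else {
    pts <- do.call(rbind, lapply(unique(record$atoms$chain), function(ch) {
      m <- ca_coords(record, ch)
      h <- convex_hull_3d(m)
      m[h$vertices, , drop = FALSE]
    }))
  }
  a1 <- hull_area_2d(project_to_plane(pts, assessment$planes[[1]]))
  a2 <- hull_area_2d(project_to_plane(pts, assessment$planes[[2]]))
  profile$area_by_plane <- c(a1, a2)
  profile$membrane_area <- max(a1, a2)
  profile
}

#' Distribute complex-formation fluxes into gene-level spatial allocation
#'
#' Each complex's volume (and membrane footprint, when present) is
#' multiplied by its formation flux and distributed to its genes in
#' proportion to the copy-number stoichiometry (`mode = "copies"`, the
#' default) or to copies times subunit length (`mode = "aa"`).  The
#' translation flux of a gene is formation flux times its copy count.
#' Conservation holds exactly: per complex, gene volume fluxes sum to
#' volume times flux.
#'
#' @param profiles named list of `geometric_profile`s (by complex id).
#' @param flux_table data frame (or TSV path) with columns `complex_id`,
#'   `formation_flux` (>= 0).
#' @param targets list of [complex_target()]s supplying stoichiometries.
#' @param registry a [gene_registry()] (needed for `mode = "aa"`).
#' @param mode proportionality rule.
#' @return Data frame: `complex_id`, `gene_id`, `copies`,
#'   `translation_flux`, `volume_flux`, `area_flux`.
#' @export
allocate_fluxes <- function(profiles, flux_table, targets, registry = NULL,
                            mode = c("copies", "aa")) {
  mode <- match.arg(mode)
  if (is.character(flux_table))
    flux_table <- utils::read.delim(flux_table, stringsAsFactors = FALSE)
  stopifnot(all(c("complex_id", "formation_flux") %in% names(flux_table)))
  tmap <- stats::setNames(targets,
                          vapply(targets, `[[`, character(1), "complex_id"))
  rows <- list()
  for (i in seq_len(nrow(flux_table))) {
    cid <- flux_table$complex_id[i]
    flux <- flux_table$formation_flux[i]
    if (flux == 0) next
    prof <- profiles[[cid]]
    if (is.null(prof))
      stop("fluxed complex without geometric profile: ", cid)
    tgt <- tmap[[cid]]
    if (is.null(tgt))
      stop("fluxed complex without target stoichiometry: ", cid)
    st <- tgt$stoichiometry
    w <- if (mode == "copies") as.numeric(st) else {
      if (is.null(registry)) stop("mode='aa' needs a gene registry")
      as.numeric(st) * registry[names(st), "length"]
    }
    share <- w / sum(w)
    vol_flux <- prof$total_volume * flux
    area_flux <- if (is.na(prof$membrane_area)) NA_real_ else
      prof$membrane_area * flux
    rows[[length(rows) + 1L]] <- data.frame(
      complex_id = cid, gene_id = names(st), copies = as.integer(st),
      translation_flux = flux * as.numeric(st),
      volume_flux = vol_flux * share,
      area_flux = if (is.na(area_flux)) NA_real_ else area_flux * share,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex_id = character(), gene_id = character(),
               copies = integer(), translation_flux = numeric(),
               volume_flux = numeric(), area_flux = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
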