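#' Read a mutation table
#'
#' TSV with columns `gene_id`, `position`, `ref_aa`, `alt_aa`, `source`
#' (`ALE`, `LTEE` or `ALLELEOME`) and optional `occurrence` (wild-type
#' allele occurrence in `[0, 1]`, alleleome rows only).  Grantham scores
#' are attached on load.
#'
#' @param path TSV file or data frame.
#' @return Data frame with an added `grantham` column.
#' @export
read_mutations <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "position", "ref_aa", "alt_aa", "source")
  stopifnot(all(need %in% names(tab)))
  m <- grantham_matrix()
  tab$grantham <- vapply(seq_len(nrow(tab)), function(i)
    m[toupper(tab$ref_aa[i]), toupper(tab$alt_aa[i])], integer(1))
  tab
}

#' Map sequence-positional items onto a structure
#'
#' Sends each (gene, position) through the chain-gene alignments to every
#' chain copy of the gene in the structure: a position in a homodimer maps
#' to two structural residues, which is why oligomerization roughly doubles
#' the count of unique proteomic positions relative to genomic ones.
#' Positions without structural coverage are reported separately, never
#' silently dropped.
#'
#' @param items data frame with columns `gene_id`, `position` (plus any
#'   payload columns, carried through).
#' @param record a `structure_record`.
#' @param alignments named list entity id -> `chain_gene_alignment`.
#' @return A `structure_annotation`: list with `mapped` (items + `chain`,
#'   `resno`) and `unresolved` (input rows with no structural residue).
#' @export
map_to_structure <- function(items, record, alignments) {
  mapped <- list()
  unresolved <- list()
  for (i in seq_len(nrow(items))) {
    hit <- map_gene_positions(record, alignments, items$gene_id[i],
                              items$position[i])
    if (nrow(hit) == 0) {
      unresolved[[length(unresolved) + 1L]] <- items[i, , drop = FALSE]
      next
    }
    block <- items[rep(i, nrow(hit)), , drop = FALSE]
    block$chain <- hit$chain
    block$resno <- hit$resno
    mapped[[length(mapped) + 1L]] <- block
  }
  bind <- function(l, proto) {
    if (length(l)) { out <- do.call(rbind, l); rownames(out) <- NULL; out }
    else proto[0, , drop = FALSE]
  }
  proto_m <- items[0, , drop = FALSE]
  proto_m$chain <- character(0); proto_m$resno <- integer(0)
  structure(list(mapped = bind(mapped, proto_m),
                 unresolved = bind(unresolved, items[0, , drop = FALSE])),
            class = "structure_annotation")
}

residue_coords <- function(record, chain, resno) {
  idx <- match(paste(chain, resno),
               paste(record$atoms$chain, record$atoms$resno))
  as.matrix(record$atoms[idx[!is.na(idx)], c("x", "y", "z"), drop = FALSE])
}

#' Minimum CA distance from a residue set to a domain
#'
#' Minimum Euclidean CA-CA distance over all pairs of (query copy, domain
#' residue).  An empty domain yields `NA` (undefined, not zero).
#'
#' @param query data frame `chain`, `resno` (e.g. all structural copies of
#'   a mutation).
#' @param domain data frame `chain`, `resno`.
#' @param record a `structure_record`.
#' @return Distance in angstroms, or `NA_real_`.
#' @export
min_distance_to_domain <- function(query, domain, record) {
  if (nrow(domain) == 0 || nrow(query) == 0) return(NA_real_)
  qm <- residue_coords(record, query$chain, query$resno)
  dm <- residue_coords(record, domain$chain, domain$resno)
  if (nrow(qm) == 0 || nrow(dm) == 0) return(NA_real_)
  d2 <- outer(rowSums(qm^2), rowSums(dm^2), "+") - 2 * qm %*% t(dm)
  sqrt(max(0, min(d2)))
}

#' Mutation-domain proximity report
#'
#' For every mutation: its nearest functional domain, the distance to it,
#' the Grantham severity, whether the mutation lies inside a domain
#' (presence/absence), and a proximity flag.  With `mode = "spatial"`
#' (default) the distance is the minimum CA-CA distance over all structural
#' copies and the default cutoff is 3.8 angstroms (one canonical CA-CA
#' bond, i.e. "within one amino-acid length"); with `mode = "sequence"`
#' distance is in residues along the gene and the cutoff defaults to 1.
#'
#' @param mutations mutation data frame (see [read_mutations()]).
#' @param domains data frame `gene_id`, `kind`, `position` (one row per
#'   domain residue).
#' @param record a `structure_record`.
#' @param alignments entity -> alignment list.
#' @param cutoff proximity cutoff (angstroms or residues, per `mode`).
#' @param mode `"spatial"` or `"sequence"`.
#' @param severe_cutoff Grantham class boundary.
#' @return Data frame, one row per mutation: mutation columns plus
#'   `nearest_domain`, `distance`, `in_domain`, `proximal`, `severe`.
#' @export
proximity_report <- function(mutations, domains, record, alignments,
                             cutoff = NULL, mode = c("spatial", "sequence"),
                             severe_cutoff = 100) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "spatial") 3.8 else 1
  if (!"grantham" %in% names(mutations)) mutations <- read_mutations(mutations)
  kinds <- sort(unique(domains$kind))
  dom_map <- lapply(kinds, function(k) {
    d <- domains[domains$kind == k, , drop = FALSE]
    list(rows = d, mapped = map_to_structure(d, record, alignments)$mapped)
  })
  names(dom_map) <- kinds
  rows <- lapply(seq_len(nrow(mutations)), function(i) {
    mu <- mutations[i, , drop = FALSE]
    in_dom <- any(vapply(dom_map, function(dk)
      any(dk$rows$gene_id == mu$gene_id & dk$rows$position == mu$position),
      logical(1)))
    if (mode == "spatial") {
      mq <- map_to_structure(mu, record, alignments)$mapped
      dists <- vapply(dom_map, function(dk)
        min_distance_to_domain(mq, dk$mapped, record), numeric(1))
    } else {
      dists <- vapply(dom_map, function(dk) {
        d <- dk$rows[dk$rows$gene_id == mu$gene_id, , drop = FALSE]
        if (nrow(d) == 0) NA_real_ else min(abs(d$position - mu$position))
      }, numeric(1))
    }
    if (all(is.na(dists))) {
      nearest <- NA_character_; dist <- NA_real_
    } else {
      nearest <- kinds[which.min(dists)]
      dist <- min(dists, na.rm = TRUE)
    }
    data.frame(mu, nearest_domain = nearest, distance = dist,
               in_domain = in_dom,
               proximal = !is.na(dist) && dist <= cutoff,
               severe = mu$grantham > severe_cutoff,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Geometric protein-protein interface residues
#'
#' A residue is an interface residue at a threshold when its CA lies within
#' that distance of any CA on a *different* chain.  The relation is
#' symmetric: both partners of a qualifying pair are reported.
#'
#' @param record a `structure_record` (>= 2 chains for a non-empty result).
#' @param threshold distance cutoff in angstroms; the conventional choices
#'   are 3, 5, 7.5 and 10.
#' @return List with `residues` (data frame `chain`, `resno`) and `pairs`
#'   (data frame of qualifying cross-chain pairs with distances).
#' @export
detect_interfaces <- function(record, threshold = 5) {
  a <- record$atoms
  empty <- list(residues = empty_res_df(),
                pairs = data.frame(chain1 = character(), resno1 = integer(),
                                   chain2 = character(), resno2 = integer(),
                                   distance = numeric(),
                                   stringsAsFactors = FALSE))
  if (length(unique(a$chain)) < 2) return(empty)
  m <- as.matrix(a[, c("x", "y", "z")])
  d2 <- outer(rowSums(m^2), rowSums(m^2), "+") - 2 * m %*% t(m)
  d2[d2 < 0] <- 0
  cross <- outer(a$chain, a$chain, "!=")
  hit <- which(cross & upper.tri(d2) & d2 <= threshold^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  pairs <- data.frame(chain1 = a$chain[hit[, 1]], resno1 = a$resno[hit[, 1]],
                      chain2 = a$chain[hit[, 2]], resno2 = a$resno[hit[, 2]],
                      distance = sqrt(d2[hit]), stringsAsFactors = FALSE)
  res <- unique(rbind(
    data.frame(chain = pairs$chain1, resno = pairs$resno1,
               stringsAsFactors = FALSE),
    data.frame(chain = pairs$chain2, resno = pairs$resno2,
               stringsAsFactors = FALSE)))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  list(residues = res, pairs = pairs)
}

#' Detect disulfide bridges
#'
#' All cysteine pairs whose sulfur (SG) atoms lie strictly within
#' `threshold` angstroms (default 3).  When a record carries no sulfur
#' coordinates the CA positions of cysteines are used instead and the
#' result is flagged (`used_ca`).
#'
#' @param record a `structure_record`.
#' @param threshold distance cutoff in angstroms.
#' @return Data frame `chain1`, `resno1`, `chain2`, `resno2`, `distance`,
#'   `used_ca`, deduplicated and sorted.
#' @export
detect_disulfides <- function(record, threshold = 3) {
  empty <- data.frame(chain1 = character(), resno1 = integer(),
                      chain2 = character(), resno2 = integer(),
                      distance = numeric(), used_ca = logical(),
                      stringsAsFactors = FALSE)
  used_ca <- nrow(record$sg) == 0
  s <- if (used_ca) {
    cys <- record$atoms[record$atoms$aa == "C", , drop = FALSE]
    cys[, c("chain", "resno", "x", "y", "z"), drop = FALSE]
  } else record$sg
  if (nrow(s) < 2) return(empty)
  m <- as.matrix(s[, c("x", "y", "z")])
  d2 <- outer(rowSums(m^2), rowSums(m^2), "+") - 2 * m %*% t(m)
  d2[d2 < 0] <- 0
  hit <- which(upper.tri(d2) & d2 < threshold^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- data.frame(chain1 = s$chain[hit[, 1]], resno1 = s$resno[hit[, 1]],
                    chain2 = s$chain[hit[, 2]], resno2 = s$resno[hit[, 2]],
                    distance = sqrt(d2[hit]), used_ca = used_ca,
                    stringsAsFactors = FALSE)
  # exclude self-pairs (same residue) that can appear with altloc SG copies
  out <- out[!(out$chain1 == out$chain2 & out$resno1 == out$resno2), ,
             drop = FALSE]
  out <- unique(out)
  out <- out[order(out$chain1, out$resno1, out$chain2, out$resno2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
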