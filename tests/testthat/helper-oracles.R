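# Shared helpers: direct object builders and independent brute-force
# oracles the implementation is checked against.  The oracles deliberately
# use the most naive formulation (exhaustive products, all-pairs scans,
# direct SVD fits) and share no code with the package internals.

mk_registry <- function(...) {
  seqs <- c(...)
  gene_registry(names(seqs), seqs)
}

rand_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# a structure_record built directly from a CA table (chain, aa, x, y, z)
mk_record <- function(atoms, structure_id = "S1", source = "PDB",
                      sg = NULL, model_metrics = NULL) {
  atoms <- do.call(rbind, lapply(split(atoms, atoms$chain), function(sub) {
    sub$resno <- seq_len(nrow(sub))
    sub
  }))
  rownames(atoms) <- NULL
  atoms$auth_resno <- atoms$resno
  if (!"b" %in% names(atoms)) atoms$b <- 0
  chains <- unique(atoms$chain)
  seqs <- vapply(chains, function(ch)
    paste(atoms$aa[atoms$chain == ch], collapse = ""), character(1))
  uniq <- unique(seqs)
  entities <- lapply(seq_along(uniq), function(i) {
    ch <- chains[seqs == uniq[i]]
    list(entity_id = as.character(i), chain_ids = ch, sequence = uniq[i],
         copy_count = length(ch))
  })
  names(entities) <- as.character(seq_along(uniq))
  if (is.null(sg))
    sg <- data.frame(chain = character(), resno = integer(), x = numeric(),
                     y = numeric(), z = numeric(), stringsAsFactors = FALSE)
  structure(list(structure_id = structure_id, source = source,
                 atoms = atoms, sg = sg, entities = entities,
                 model_metrics = model_metrics, unusable = FALSE),
            class = "structure_record")
}

# identity alignment of a gene onto an entity (same length, same sequence)
mk_alignment <- function(structure_id, entity_id, gene_id, n,
                         identity = 1) {
  structure(list(structure_id = structure_id, entity_id = entity_id,
                 gene_id = gene_id, identity = identity,
                 residue_map = stats::setNames(seq_len(n), seq_len(n)),
                 low_identity = identity < 0.2),
            class = "chain_gene_alignment")
}

# multi-chain record from one compact globule per chain
globule_record <- function(structure_id, chain_seqs, source = "PDB") {
  atoms <- do.call(rbind, lapply(seq_along(chain_seqs), function(i) {
    co <- synth_globule(nchar(chain_seqs[[i]]),
                        origin = c((i - 1) * 40, 0, 0))
    data.frame(chain = names(chain_seqs)[i],
               aa = strsplit(chain_seqs[[i]], "")[[1]],
               x = co[, 1], y = co[, 2], z = co[, 3],
               stringsAsFactors = FALSE)
  }))
  mk_record(atoms, structure_id = structure_id, source = source)
}

# pseudo-structure stub for matching/curation tests
qc_pass_all <- function(obs) {
  if (length(obs) == 0) return(list())
  lapply(stats::setNames(seq_along(obs), paste0("S", seq_along(obs))),
         function(i) list(pass = TRUE, reasons = character(0)))
}

mk_ps <- function(structure_id, stoich, quality = 1, source = "PDB") {
  st <- stoich[order(names(stoich))]
  structure(list(structure_id = structure_id, source = source,
                 assignment = NULL,
                 per_entity_identity = NULL,
                 gene_stoichiometry = stats::setNames(as.integer(st),
                                                      names(st)),
                 signature = stoich_signature(st), quality = quality,
                 ps_id = paste0(structure_id, "/",
                                paste(names(st), collapse = "+"))),
            class = "pseudo_structure")
}

# --- oracle: exhaustive multiset cover ------------------------------------
# every multiset of parts (indices, repeats allowed) whose stoichiometries
# sum exactly to the target; canonical non-decreasing index order
oracle_multiset_cover <- function(target, part_stoichs) {
  genes <- names(target)
  vecs <- lapply(part_stoichs, function(st) {
    v <- stats::setNames(integer(length(genes)), genes)
    if (!all(names(st) %in% genes)) return(NULL)
    v[names(st)] <- st
    v
  })
  sols <- list()
  recurse <- function(rem, i, acc) {
    if (all(rem == 0L)) {
      sols[[length(sols) + 1L]] <<- acc
      return(invisible())
    }
    if (i > length(vecs)) return(invisible())
    v <- vecs[[i]]
    recurse(rem, i + 1L, acc)          # part i used zero times
    if (!is.null(v)) {
      cnt <- 0L
      while (all(v <= rem)) {          # ... or 1, 2, ... times
        rem <- rem - v
        cnt <- cnt + 1L
        recurse(rem, i + 1L, c(acc, rep(i, cnt)))
      }
    }
  }
  recurse(stats::setNames(as.integer(target), genes), 1L, integer(0))
  unique(lapply(sols, sort))
}

# --- oracle: all-pairs cross-chain contacts -------------------------------
oracle_interfaces <- function(atoms, threshold) {
  res <- list()
  for (i in seq_len(nrow(atoms))) for (j in seq_len(nrow(atoms))) {
    if (i == j || atoms$chain[i] == atoms$chain[j]) next
    d <- sqrt(sum((c(atoms$x[i], atoms$y[i], atoms$z[i]) -
                     c(atoms$x[j], atoms$y[j], atoms$z[j]))^2))
    if (d <= threshold)
      res[[length(res) + 1L]] <- paste(atoms$chain[i], atoms$resno[i])
  }
  out <- unlist(res)
  if (is.null(out)) character(0) else sort(unique(out))
}

# --- oracle: direct total-least-squares plane normal ----------------------
oracle_plane_normal <- function(points) {
  ctr <- colMeans(points)
  svd(sweep(points, 2, ctr))$v[, 3]
}

angle_between <- function(a, b) {
  cosv <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, cosv))
}

# random rotation matrix (uniform via QR of gaussian)
rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# fixture bundle shared across integration-style tests (built once)
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "oligoscape_bundle")
      cache <<- make_synthetic_proteome(dir, seed = 421)
    }
    cache
  }
})

run_fixture_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- fixture_bundle()
      cfg <- default_run_config()
      for (k in names(b$paths)) if (k %in% names(cfg))
        cfg[[k]] <- b$paths[[k]]
      cfg$out_dir <- file.path(tempdir(), "oligoscape_out")
      cache <<- list(bundle = b,
                     result = suppressMessages(run_pipeline(cfg)))
    }
    cache
  }
})
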