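test_that("UniProt transmembrane spans split into termini and embedded core", {
  lines <- c("ID   gX   fixture",
             "FT   TOPO_DOM        1..9",
             "FT                   /note=\"Periplasmic\"",
             "FT   TRANSMEM        10..30",
             "FT                   /note=\"Helical\"",
             "FT   TOPO_DOM        31..60",
             "FT                   /note=\"Cytoplasmic\"")
  ft <- parse_uniprot_features(lines)
  expect_equal(ft$kind, c("TOPO_DOM", "TRANSMEM", "TOPO_DOM"))
  expect_equal(ft$start, c(1L, 10L, 31L))

  n <- 60
  co <- synth_line(n, spacing = 1.5, dir = c(0, 0, 1),
                   origin = c(0, 0, -20))
  co[, 1] <- seq_len(n) %% 5   # avoid collinearity
  rec <- mk_record(data.frame(chain = "A", aa = strsplit(rand_seq(n), "")[[1]],
                              x = co[, 1], y = co[, 2], z = co[, 3]))
  als <- list("1" = mk_alignment("S1", "1", "gX", n))
  sets <- build_crossing_sets(rec, als, uniprot_features = ft)
  s <- sets[["UNIPROT"]]
  expect_equal(sort(s$embedded$resno), 11:29)
  labels <- vapply(s$groups, attr, character(1), "label")
  g_by <- stats::setNames(s$groups, labels)
  expect_equal(g_by[["periplasmic"]]$resno, 10L)
  expect_equal(g_by[["cytoplasmic"]]$resno, 30L)
})

test_that("topology alternation assigns outside spans to alternating leaflets", {
  topo <- paste0(strrep("O", 9), strrep("M", 21), strrep("I", 10),
                 strrep("M", 20), strrep("O", 10))
  tm <- stats::setNames(topo, "gY")
  n <- nchar(topo)
  co <- cbind(seq_len(n) %% 7, seq_len(n) %% 3, seq(-20, 20, length.out = n))
  rec <- mk_record(data.frame(chain = "A", aa = strsplit(rand_seq(n), "")[[1]],
                              x = co[, 1], y = co[, 2], z = co[, 3]))
  als <- list("1" = mk_alignment("S1", "1", "gY", n))
  sets <- build_crossing_sets(rec, als, tmhmm = tm)
  s <- sets[["DEEPTMHMM"]]
  # soluble spans 1..9 and 61..70 share leaflet L1, span 31..40 is L2, so
  # span termini 10 and 60 land in L1 while 30 and 41 land in L2
  g_by <- stats::setNames(s$groups, vapply(s$groups, attr, character(1),
                                           "label"))
  expect_setequal(g_by[["L1"]]$resno, c(10L, 60L))
  expect_setequal(g_by[["L2"]]$resno, c(30L, 41L))
  reg <- topology_regions(topo)
  expect_equal(reg$type, c("O", "M", "I", "M", "O"))
})

test_that("OPM dummy atoms split into leaflet point sets by z sign", {
  grid <- as.matrix(expand.grid(seq(0, 20, 5), seq(0, 10, 5)))
  dum <- rbind(cbind(grid, 15), cbind(grid, -15))
  atoms <- data.frame(chain = "A", resno = 1:4, aa = c("M", "K", "T", "A"),
                      x = c(0, 5, 10, 15), y = c(0, 3, 1, 2),
                      z = c(-5, 0, 5, 25))
  f <- file.path(tempdir(), "opm_fix.pdb")
  write_structure_fixture(atoms, f, dum_points = dum)
  opm <- parse_opm(f)
  expect_equal(nrow(opm$dummy$L1), nrow(grid))
  expect_true(all(opm$dummy$L1[, 3] > 0))
  expect_true(all(opm$dummy$L2[, 3] < 0))
})

test_that("plane fitting is exact on coplanar points and drops outliers", {
  # 5 points exactly on z = 0: normal (0,0,1) up to sign, zero error
  pts <- cbind(c(0, 1, 2, 0.5, 1.7), c(0, 0.3, 1, 2, 0.1), 0)
  p <- fit_membrane_plane(pts)
  expect_lt(angle_between(p$normal, c(0, 0, 1)), 1e-9)
  expect_lt(p$fit_error, 1e-18)
  expect_equal(p$n_removed, 0L)

  # 6 points: 5 near z = 0 plus one at z = 20 -> the outlier is excluded
  set.seed(21)
  inl <- cbind(runif(5, 0, 10), runif(5, 0, 10),
               runif(5, -0.1, 0.1))
  out <- rbind(inl, c(5, 5, 20))
  p2 <- fit_membrane_plane(out)
  expect_equal(p2$n_removed, 1L)
  expect_lt(angle_between(p2$normal, c(0, 0, 1)) * 180 / pi, 1)

  # exactly 4 points: direct fit, no iteration
  p3 <- fit_membrane_plane(rbind(c(0, 0, 0), c(1, 0, 0.1),
                                 c(0, 1, -0.1), c(1, 1, 0)))
  expect_equal(p3$n_removed, 0L)

  expect_error(fit_membrane_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
  expect_error(fit_membrane_plane(rbind(c(0, 0, 0), c(1, 0, 0),
                                        c(2, 0, 0), c(3, 0, 0))),
               "collinear")
})

test_that("plane recovery matches the planted normal over random poses", {
  set.seed(77)
  for (i in 1:50) {
    R <- rand_rotation()
    k <- sample(5:20, 1)
    flat <- cbind(runif(k, -10, 10), runif(k, -10, 10), 0)
    pts <- flat %*% t(R)
    p <- fit_membrane_plane(pts)
    expect_lt(angle_between(p$normal, R[, 3]), 1e-6)
    # and agrees with a direct SVD oracle
    expect_lt(angle_between(p$normal, oracle_plane_normal(pts)), 1e-9)
  }
})

# exact plane objects keep the boundary suite free of fitting round-off
plane_z <- function(z)
  structure(list(normal = c(0, 0, 1), offset = z, fit_error = 0,
                 support = NULL, n_removed = 0L), class = "membrane_plane")
tilted_plane <- function(angle_deg) {
  th <- angle_deg * pi / 180
  structure(list(normal = c(sin(th), 0, cos(th)), offset = 30,
                 fit_error = 0, support = NULL, n_removed = 0L),
            class = "membrane_plane")
}
slab_points <- function(extent = 20) {
  g <- as.matrix(expand.grid(seq(0, extent, length.out = 5),
                             seq(0, extent, length.out = 5),
                             c(5, 15, 25)))
  g
}

test_that("viability thresholds behave strictly or inclusively at bounds", {
  p0 <- plane_z(0)
  # thickness band is inclusive: 12 and 45 pass, 11.9 and 45.1 fail
  for (tt in c(12, 45)) {
    a <- assess_membrane(p0, plane_z(tt),
                         cbind(runif(10, 0, 60), runif(10, 0, 60), tt / 2))
    expect_true(a$viable, info = paste("thickness", tt))
    expect_equal(a$thickness_A, tt)
  }
  for (tt in c(11.9, 45.1)) {
    a <- assess_membrane(p0, plane_z(tt),
                         cbind(runif(10, 0, 60), runif(10, 0, 60), tt / 2))
    expect_false(a$viable)
    expect_true("thickness" %in% a$reasons)
  }
  # angle strictly below 35 degrees
  a35 <- assess_membrane(p0, tilted_plane(35), slab_points())
  expect_false(a35$viable)
  expect_true("angle" %in% a35$reasons)
  expect_equal(a35$angle_deg, 35, tolerance = 1e-6)
  a349 <- assess_membrane(p0, tilted_plane(34.9), slab_points())
  expect_lt(a349$angle_deg, 35)
  expect_false("angle" %in% a349$reasons)
  # area strictly below 10,000 square angstroms
  big <- function(side) {
    emb <- as.matrix(expand.grid(seq(0, side, length.out = 7),
                                 seq(0, side, length.out = 7), 15))
    assess_membrane(p0, plane_z(30), emb)
  }
  exact <- big(100)      # projection is exactly 100 x 100 = 10,000
  expect_false(exact$viable)
  expect_true("area" %in% exact$reasons)
  under <- big(99.99)
  expect_true(under$viable)
  # fewer than 3 embedded points: area undefined, not viable
  few <- assess_membrane(p0, plane_z(30), cbind(1, 1, 15)[0, , drop = FALSE])
  expect_false(few$viable)
})

test_that("source deference prefers OPM, then UniProt, then DeepTMHMM", {
  p0 <- plane_z(0)
  viable_for <- function(src) {
    a <- assess_membrane(p0, plane_z(30), slab_points(), source = src)
    a
  }
  opm <- viable_for("OPM"); uni <- viable_for("UNIPROT")
  tmh <- viable_for("DEEPTMHMM")
  expect_equal(choose_source(list(uni, opm))$source, "OPM")
  expect_equal(choose_source(list(tmh, uni))$source, "UNIPROT")
  expect_equal(choose_source(list(tmh))$source, "DEEPTMHMM")
  bad <- viable_for("OPM"); bad$viable <- FALSE
  expect_equal(choose_source(list(bad, tmh))$source, "DEEPTMHMM")
  expect_null(choose_source(list(bad)))
})

membrane_record <- function(flip = FALSE) {
  # 4-TM single chain: slab between z = -15 and 15, loops at z = +-19
  mp <- oligoscape:::membrane_protein_chain(4, 15)
  co <- mp$coords
  if (flip) co[, 3] <- -co[, 3]
  n <- nrow(co)
  rec <- mk_record(data.frame(chain = "A", aa = strsplit(rand_seq(n), "")[[1]],
                              x = co[, 1], y = co[, 2], z = co[, 3]))
  list(rec = rec, topo = mp$topo, n = n)
}

mem_features <- function(topo, pos_label, neg_label, with_topo = TRUE) {
  reg <- topology_regions(topo)
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    if (r$type == "M")
      data.frame(gene_id = "gM", kind = "TRANSMEM", start = r$start,
                 end = r$end, note = "Helical", stringsAsFactors = FALSE)
    else if (with_topo)
      data.frame(gene_id = "gM", kind = "TOPO_DOM", start = r$start,
                 end = r$end,
                 note = if (r$type == "O") pos_label else neg_label,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("orientation by topological-domain majority labels both bulbs", {
  m <- membrane_record()
  ft <- mem_features(m$topo, "Periplasmic", "Cytoplasmic")
  als <- list("1" = mk_alignment("S1", "1", "gM", m$n))
  sets <- build_crossing_sets(m$rec, als, uniprot_features = ft)
  a <- assess_crossing_set(sets[["UNIPROT"]], m$rec)
  expect_true(a$viable)
  expect_equal(a$thickness_A, 30, tolerance = 1e-6)
  o <- orient_protein(m$rec, a, als, ft)
  expect_true(o$known)
  expect_equal(o$side_pos, "periplasmic")
  expect_equal(o$side_neg, "cytoplasmic")
  # manual table drives orientation when annotation is absent
  ft2 <- mem_features(m$topo, NA, NA, with_topo = FALSE)
  manual <- data.frame(structure_id = "S1", side_pos = "cytoplasmic",
                       side_neg = "periplasmic", stringsAsFactors = FALSE)
  o2 <- orient_protein(m$rec, a, als, ft2, manual)
  expect_equal(o2$method, "manual")
  expect_equal(o2$side_pos, "cytoplasmic")
  badman <- data.frame(structure_id = "S1", side_pos = "upwards",
                       side_neg = "periplasmic", stringsAsFactors = FALSE)
  expect_error(orient_protein(m$rec, a, als, ft2, badman), "must be one of")
  # neither source: unknown
  o3 <- orient_protein(m$rec, a, als, ft2, NULL)
  expect_false(o3$known)
})

test_that("compartment assignment is total and matches the planted slab", {
  m <- membrane_record()
  ft <- mem_features(m$topo, "Periplasmic", "Cytoplasmic")
  als <- list("1" = mk_alignment("S1", "1", "gM", m$n))
  meta <- data.frame(gene_id = "gM", go = "", ecocyc = "inner membrane",
                     gem = "", stringsAsFactors = FALSE)
  sets <- build_crossing_sets(m$rec, als, uniprot_features = ft)
  a <- assess_crossing_set(sets[["UNIPROT"]], m$rec)
  o <- orient_protein(m$rec, a, als, ft)
  ca <- assign_compartments(m$rec, meta, a, o, membrane_candidate = TRUE)
  expect_equal(nrow(ca), m$n)
  expect_false(anyNA(ca$compartment))
  z <- m$rec$atoms$z
  expect_true(all(ca$compartment[abs(z) <= 15] == 9))
  expect_true(all(ca$compartment[z > 15] == 8))
  expect_true(all(ca$compartment[z < -15] == 10))
})

test_that("mirroring the protein with swapped labels mirrors compartments", {
  up <- membrane_record(flip = FALSE)
  dn <- membrane_record(flip = TRUE)
  als_u <- list("1" = mk_alignment("S1", "1", "gM", up$n))
  meta <- data.frame(gene_id = "gM", go = "", ecocyc = "inner membrane",
                     gem = "", stringsAsFactors = FALSE)
  ft_u <- mem_features(up$topo, "Periplasmic", "Cytoplasmic")
  ft_d <- mem_features(dn$topo, "Periplasmic", "Cytoplasmic")
  run <- function(m, ft) {
    sets <- build_crossing_sets(m$rec, list("1" = mk_alignment("S1", "1",
                                                               "gM", m$n)),
                                uniprot_features = ft)
    a <- assess_crossing_set(sets[["UNIPROT"]], m$rec)
    o <- orient_protein(m$rec, a,
                        list("1" = mk_alignment("S1", "1", "gM", m$n)), ft)
    assign_compartments(m$rec, meta, a, o, membrane_candidate = TRUE)
  }
  cu <- run(up, ft_u)
  cd <- run(dn, ft_d)
  # residue-by-residue identical compartments: geometry flipped, labels too
  expect_equal(cu$compartment, cd$compartment)
})

test_that("keyword classification covers every soluble compartment", {
  co <- synth_globule(8)
  rec <- mk_record(data.frame(chain = "A", aa = strsplit("MKTAYIAK", "")[[1]],
                              x = co[, 1], y = co[, 2], z = co[, 3]))
  meta_of <- function(ecocyc) data.frame(gene_id = "g", go = "",
                                         ecocyc = ecocyc, gem = "",
                                         stringsAsFactors = FALSE)
  cases <- list(list("cytoplasm", 12L), list("periplasmic space", 6L),
                list("extracellular", 1L), list("", 19L),
                list("inner membrane, cytoplasm", 11L),
                list("inner membrane, periplasmic", 7L),
                list("outer membrane, periplasmic", 5L),
                list("membrane", 18L))
  for (cs in cases) {
    ca <- assign_compartments(rec, meta_of(cs[[1]]),
                              membrane_candidate = grepl("membrane|periplas",
                                                         cs[[1]]))
    expect_true(all(ca$compartment == cs[[2]]),
                info = paste("keywords:", cs[[1]]))
  }
})

test_that("membrane-gene flagging uses all four keyword sources", {
  meta <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    go = c("ion transport", "", "", ""),
    ecocyc = c("", "", "cytoplasm", ""),
    gem = c("", "murein biosynthesis", "", ""),
    stringsAsFactors = FALSE)
  ft <- data.frame(gene_id = "g4", kind = "TRANSMEM", start = 1, end = 10,
                   note = NA, stringsAsFactors = FALSE)
  ids <- flag_membrane_candidates(
    list(SA = "g1", SB = "g2", SC = "g3", SD = "g4"), meta, ft)
  expect_setequal(ids, c("SA", "SB", "SD"))
})
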