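write_fix <- function(atoms, ext = "pdb", ...) {
  path <- file.path(tempdir(), paste0("cat_", ext, "_",
                                      abs(sum(atoms$x) * 1000) %% 1e6,
                                      ".", ext))
  write_structure_fixture(atoms, path, ...)
  path
}

test_that("PDB parsing groups identical-sequence chains into one entity", {
  co <- synth_globule(12)
  atoms <- rbind(
    data.frame(chain = "A", resno = 1:12, aa = strsplit("MKTAYIAKQRQI", "")[[1]],
               x = co[, 1], y = co[, 2], z = co[, 3]),
    data.frame(chain = "B", resno = 1:12, aa = strsplit("MKTAYIAKQRQI", "")[[1]],
               x = co[, 1] + 30, y = co[, 2], z = co[, 3]))
  rec <- parse_structure(write_fix(atoms), "PDB", "toy1")
  expect_length(rec$entities, 1)
  expect_equal(rec$entities[[1]]$copy_count, 2L)
  expect_equal(rec$entities[[1]]$sequence, "MKTAYIAKQRQI")
  # entity copy counts total the file's chain count
  expect_equal(sum(vapply(rec$entities, `[[`, integer(1), "copy_count")),
               length(unique(rec$atoms$chain)))
})

test_that("mmCIF entity records drive hetero-dimer grouping", {
  co <- synth_globule(8)
  atoms <- rbind(
    data.frame(chain = "A", resno = 1:8, aa = strsplit("MKTAYIAK", "")[[1]],
               x = co[, 1], y = co[, 2], z = co[, 3]),
    data.frame(chain = "B", resno = 1:8, aa = strsplit("GHILMNPQ", "")[[1]],
               x = co[, 1] + 30, y = co[, 2], z = co[, 3]))
  rec <- parse_structure(write_fix(atoms, "cif"), "PDB", "toy2")
  expect_length(rec$entities, 2)
  expect_true(all(vapply(rec$entities, `[[`, integer(1), "copy_count") == 1L))
})

test_that("model confidence is averaged from the B-factor column", {
  co <- synth_globule(8)
  atoms <- data.frame(chain = "A", resno = 1:8,
                      aa = strsplit("MKTAYIAK", "")[[1]],
                      x = co[, 1], y = co[, 2], z = co[, 3], b = 90)
  rec <- parse_structure(write_fix(atoms), "ALPHAFOLD")
  expect_equal(rec$model_metrics$mean_confidence, 90)
})

test_that("alignment identity uses the gene length as denominator", {
  gseq <- rand_seq(100)
  reg <- mk_registry(g1 = gseq)
  ent_full <- list(entity_id = "1", chain_ids = "A", sequence = gseq,
                   copy_count = 1L)
  al <- align_gene_to_chain(reg["g1", ], ent_full, "S")
  expect_equal(al$identity, 1.0)
  expect_equal(unname(al$residue_map), 1:100)

  ent_half <- list(entity_id = "1", chain_ids = "A",
                   sequence = substr(gseq, 1, 50), copy_count = 1L)
  al2 <- align_gene_to_chain(reg["g1", ], ent_half, "S")
  expect_equal(al2$identity, 0.5)
  expect_equal(unname(al2$residue_map), 1:50)
  # monotone and injective
  expect_true(all(diff(al2$residue_map) > 0))
})

test_that("self-alignment has identity 1 on random sequences", {
  set.seed(11)
  for (i in 1:10) {
    s <- rand_seq(sample(30:120, 1))
    reg <- mk_registry(g = s)
    ent <- list(entity_id = "1", chain_ids = "A", sequence = s,
                copy_count = 1L)
    expect_equal(align_gene_to_chain(reg["g", ], ent)$identity, 1.0)
  }
})

test_that("unrelated sequences are retained but flagged low-identity", {
  set.seed(12)
  reg <- mk_registry(g = rand_seq(80))
  ent <- list(entity_id = "1", chain_ids = "A",
              sequence = paste(rep("W", 60), collapse = ""),
              copy_count = 1L)
  al <- align_gene_to_chain(reg["g", ], ent)
  expect_lt(al$identity, 0.2)
  expect_true(al$low_identity)
})

test_that("string-like tails are trimmed and trimming is idempotent", {
  set.seed(13)
  glob <- synth_globule(64)
  n_glob <- nrow(glob)
  tail_start <- glob[n_glob, ] + c(3.8, 0, 0)
  tail <- synth_line(30, origin = tail_start, dir = c(1, 0, 0))
  coords <- rbind(glob, tail)
  atoms <- data.frame(chain = "A", resno = seq_len(nrow(coords)),
                      aa = strsplit(rand_seq(nrow(coords)), "")[[1]],
                      x = coords[, 1], y = coords[, 2], z = coords[, 3])
  rec <- parse_structure(write_fix(atoms), "ITASSER")
  trimmed <- trim_itasser(rec)
  # the straight tail goes, the compact globule stays
  expect_gte(trimmed$trimmed_n, 25)
  expect_lte(nrow(trimmed$atoms), n_glob + 5)
  expect_false(trimmed$unusable)
  again <- trim_itasser(trimmed)
  expect_equal(again$trimmed_n, 0L)
  expect_equal(again$atoms, trimmed$atoms)

  # a compact globule alone is already a fixed point
  gl_atoms <- atoms[seq_len(n_glob), ]
  rec2 <- parse_structure(write_fix(gl_atoms), "ITASSER")
  expect_equal(trim_itasser(rec2)$trimmed_n, 0L)

  # a fully extended chain is removed entirely and flagged unusable
  line <- synth_line(40)
  ln_atoms <- data.frame(chain = "A", resno = 1:40,
                         aa = strsplit(rand_seq(40), "")[[1]],
                         x = line[, 1], y = line[, 2], z = line[, 3])
  rec3 <- parse_structure(write_fix(ln_atoms), "ITASSER")
  expect_true(trim_itasser(rec3)$unusable)
})

test_that("SWISS QC gate applies all four thresholds fail-safe", {
  mk <- function(metrics) {
    co <- synth_globule(8)
    mk_record(data.frame(chain = "A", aa = strsplit("MKTAYIAK", "")[[1]],
                         x = co[, 1], y = co[, 2], z = co[, 3]),
              source = "SWISS", model_metrics = metrics)
  }
  good_al <- mk_alignment("S", "1", "g", 8, identity = 0.8)
  ok <- list(GMQE = 0.6, QMN4 = -3, QSPRD = 0.6)

  expect_true(qc_model(mk(ok), good_al)$pass)
  r <- qc_model(mk(list(GMQE = 0.4, QMN4 = -3, QSPRD = 0.6)), good_al)
  expect_false(r$pass)
  expect_match(r$reasons, "GMQE")
  expect_false(qc_model(mk(list(GMQE = 0.6, QMN4 = -5, QSPRD = 0.6)),
                        good_al)$pass)
  expect_false(qc_model(mk(ok),
                        mk_alignment("S", "1", "g", 8, 0.6))$pass)
  # missing metric fails
  miss <- qc_model(mk(list(GMQE = 0.6, QMN4 = -3)), good_al)
  expect_false(miss$pass)
  expect_match(miss$reasons, "QSPRD")
  # non-SWISS sources pass this gate
  rec <- mk(ok); rec$source <- "PDB"
  expect_true(qc_model(rec, good_al)$pass)
})

test_that("structures without CA atoms are rejected", {
  path <- file.path(tempdir(), "noca.pdb")
  writeLines(c("HEADER", "END"), path)
  expect_error(parse_structure(path, "PDB"), "CA|parse")
})
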