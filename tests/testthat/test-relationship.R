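test_that("relationship structures enforce symmetry and labeling", {
  m <- matrix(c(1, 0.5, 0.4, 1), 2, 2)
  expect_error(relationship_structure(m, "A", ids = c("a", "b")),
               "not symmetric")
  expect_error(relationship_structure(diag(2), "A"), "ids")
  ok <- relationship_structure(diag(2), "A", ids = c("a", "b"))
  expect_equal(ok$kind, "A")
})

test_that("H equals A when G equals the pedigree block", {
  ds <- small_dataset(seed = 4, n_snps = 50)
  A <- relationship_matrix(ds$ped)
  gids <- ds$genotypes$animal_ids
  A22 <- relationship_matrix(ds$ped, ids = gids)
  Gfake <- relationship_structure(A22$values, "G")
  H <- build_H_direct(A, Gfake, gids)
  expect_lt(max(abs(H$values - A$values)), 1e-10)
  A22$kind <- "A22"
  Hi <- build_H_inverse(relationship_inverse(ds$ped),
                        invert_relationship(Gfake),
                        invert_relationship(A22), gids)
  expect_lt(max(abs(Hi$values - relationship_inverse(ds$ped)$values)),
            1e-8)
})

test_that("with no genotyped animals H reduces to A", {
  ped <- nuclear_pedigree()
  A <- relationship_matrix(ped)
  H <- build_H_direct(A, relationship_structure(matrix(1, 0, 0), "G",
                                                ids = character(0)),
                      character(0))
  expect_equal(as.matrix(H$values), as.matrix(A$values))
  Hi <- build_H_inverse(relationship_inverse(ped), NULL, NULL,
                        character(0))
  expect_equal(as.matrix(Hi$values),
               as.matrix(relationship_inverse(ped)$values))
})

test_that("shortcut H inverse equals the dense inverse of the direct H", {
  ds <- small_dataset(seed = 8, n_snps = 200)
  A <- relationship_matrix(ds$ped)
  gids <- ds$genotypes$animal_ids
  A22 <- relationship_matrix(ds$ped, ids = gids)
  A22$kind <- "A22"
  G <- build_genomic_relationship(
    scale_genotypes(qc_snps(ds$genotypes)$genotypes))
  Gb <- blend_genomic(G, A22, 0.99)
  H <- build_H_direct(A, Gb, gids)
  Hi <- build_H_inverse(relationship_inverse(ds$ped),
                        invert_relationship(Gb),
                        invert_relationship(A22), gids)
  dense <- solve(as.matrix(H$values))
  expect_lt(max(abs(as.matrix(Hi$values) - dense)), 1e-8)
  # and the genotyped block of H is exactly the blended G
  expect_equal(as.matrix(H$values)[gids, gids], as.matrix(Gb$values))
})

test_that("id mismatches between A and G are reported", {
  ds <- small_dataset(seed = 4, n_snps = 50)
  A <- relationship_matrix(ds$ped)
  G <- build_genomic_relationship(
    scale_genotypes(qc_snps(ds$genotypes)$genotypes))
  expect_error(build_H_direct(A, G, c(G$ids[-1], "ghost")),
               "ghost")
  expect_error(build_H_direct(A, G, G$ids[-1]), "exactly")
})

test_that("singular G triggers the blending hint", {
  # 3 animals, 1 SNP: rank-1 G
  g <- genotype_matrix(matrix(c(0L, 1L, 2L), 3),
                       animal_ids = c("a", "b", "c"))
  G <- build_genomic_relationship(scale_genotypes(g))
  expect_error(invert_relationship(G), "blend")
})

test_that("tuned G matches the pedigree block's mean diagonal and off-diagonal", {
  ds <- small_dataset(seed = 10, n_snps = 120)
  gids <- ds$genotypes$animal_ids
  A22 <- relationship_matrix(ds$ped, ids = gids)
  G <- build_genomic_relationship(
    scale_genotypes(qc_snps(ds$genotypes)$genotypes))
  Gt <- tune_genomic(G, A22)
  expect_equal(mean(diag(as.matrix(Gt$values))),
               mean(diag(as.matrix(A22$values))), tolerance = 1e-10)
  expect_equal(mean(as.matrix(Gt$values)), mean(as.matrix(A22$values)),
               tolerance = 1e-10)
})

test_that("relationship export round-trips dense and triplet forms", {
  ped <- nuclear_pedigree()
  A <- relationship_matrix(ped)
  path <- withr::local_tempfile(fileext = ".csv")
  write_relationship(A, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]),
               as.matrix(A$values), ignore_attr = TRUE)
  Ai <- relationship_inverse(ped)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_relationship(Ai, path2)
  trip <- utils::read.csv(path2)
  M <- matrix(0, 4, 4, dimnames = list(Ai$ids, Ai$ids))
  for (i in seq_len(nrow(trip))) {
    M[trip$row_id[i], trip$col_id[i]] <- trip$value[i]
    M[trip$col_id[i], trip$row_id[i]] <- trip$value[i]
  }
  expect_equal(M, as.matrix(Ai$values), tolerance = 1e-12)
})
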