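test_that("cleavable-bond detection separates urethane from ester", {
  cb <- find_cleavable_bonds(mol_from_smiles("CNC(=O)OC")[[1]])
  expect_equal(nrow(cb), 1)
  expect_equal(cb$kind, "urethane")
  expect_equal(nrow(find_cleavable_bonds(mol_from_smiles("CCO")[[1]])), 0)
  # polyester-polyol dimer carries both motifs
  both <- find_cleavable_bonds(mol_from_smiles(
    "CC(OC(=O)NC)C(=O)OCCC(C)C")[[1]])
  expect_gte(sum(both$kind == "urethane"), 1)
  expect_gte(sum(both$kind == "ester"), 1)
  # carbonyl atoms really are double-bonded partners
  m <- mol_from_smiles("CNC(=O)OC")[[1]]
  bonds <- pf_bonds(m)
  cb1 <- find_cleavable_bonds(m)
  hit <- bonds[(bonds$a1 == cb1$carbonyl_c & bonds$a2 == cb1$carbonyl_o) |
               (bonds$a2 == cb1$carbonyl_c & bonds$a1 == cb1$carbonyl_o), ]
  expect_equal(hit$order, 2)
})

test_that("published example distances classify as productive at 4.5 A", {
  for (d in list(c(4.0, 2.6, 3.7), c(3.9, 3.1, 4.3))) {
    fx <- make_site_fixture(d[1], d[2], d[3])
    cls <- classify_pose(fx$pose, fx$receptor, fx$site)
    expect_true(cls$productive)
    expect_equal(cls$d_ser, d[1], tolerance = 1e-6)
    expect_equal(cls$d_oxy1, d[2], tolerance = 1e-6)
    expect_equal(cls$d_oxy2, d[3], tolerance = 1e-6)
    expect_equal(cls$bond_kind, "urethane")
  }
})

test_that("the threshold is inclusive and distant poses are rejected", {
  at <- make_site_fixture(4.5, 4.5, 4.5)
  expect_true(classify_pose(at$pose, at$receptor, at$site)$productive)
  over <- make_site_fixture(4.6, 1.0, 1.0)
  expect_false(classify_pose(over$pose, over$receptor, over$site)$productive)
  far <- make_site_fixture(10, 1.0, 1.0)
  expect_false(classify_pose(far$pose, far$receptor, far$site)$productive)
  zero <- make_site_fixture(0, 0, 0)
  cls <- classify_pose(zero$pose, zero$receptor, zero$site)
  expect_true(cls$productive)
  expect_equal(cls$d_ser, 0)
})

test_that("any oxyanion distance over the threshold is disqualifying", {
  fx <- make_site_fixture(2.0, 5.0, 1.0)
  expect_false(classify_pose(fx$pose, fx$receptor, fx$site)$productive)
  fx2 <- make_site_fixture(2.0, 1.0, 5.0)
  expect_false(classify_pose(fx2$pose, fx2$receptor, fx2$site)$productive)
})

test_that("productive sets are monotone in the threshold", {
  set.seed(99)
  fixtures <- replicate(12, make_site_fixture(runif(1, 2, 7),
                                              runif(1, 2, 7),
                                              runif(1, 2, 7)),
                        simplify = FALSE)
  thresholds <- c(3, 4.5, 6, 8)
  verdicts <- vapply(thresholds, function(t)
    vapply(fixtures, function(fx)
      classify_pose(fx$pose, fx$receptor, fx$site,
                    threshold = t)$productive, logical(1)),
    logical(length(fixtures)))
  for (k in seq_len(length(thresholds) - 1)) {
    expect_true(all(verdicts[, k] <= verdicts[, k + 1]))
  }
})

test_that("nearest-bond selection equals the brute-force minimum", {
  # ligand with three cleavable bonds (two urethanes + one ester)
  smi <- "CNC(=O)OCCOC(=O)CCC(=O)OCCOC(=O)NC"
  lig <- mol_from_smiles(smi, "multi")[[1]]
  cb <- find_cleavable_bonds(lig)
  expect_gte(nrow(cb), 3)
  set.seed(7)
  for (rep in 1:20) {
    xyz <- matrix(rnorm(pf_natoms(lig) * 3, sd = 4), ncol = 3)
    pose <- structure(list(id = "multi", pose = 1L,
                           atoms = data.frame(elem = pf_elements(lig),
                                              x = xyz[, 1], y = xyz[, 2],
                                              z = xyz[, 3]),
                           bonds = pf_bonds(lig)),
                      class = "ligand_pose")
    fx <- make_site_fixture(3, 3, 3) # supplies receptor + site only
    res <- pf_resolve_site(fx$receptor, fx$site)
    d_all <- apply(xyz[cb$carbonyl_c, , drop = FALSE], 1,
                   function(p) dist3(p, res$ser))
    cls <- classify_pose(pose, fx$receptor, fx$site)
    expect_equal(cls$d_ser, min(d_all), tolerance = 1e-9)
    expect_equal(cls$bond_kind, cb$kind[which.min(d_all)])
  }
})

test_that("poses without cleavable bonds are flagged, not errored", {
  fx <- make_site_fixture(3, 3, 3)
  alkane <- mol_from_smiles("CCCCCC", "alkane")[[1]]
  pose <- structure(list(id = "alkane", pose = 1L,
                         atoms = data.frame(elem = pf_elements(alkane),
                                            x = 1:6, y = 0, z = 0),
                         bonds = pf_bonds(alkane)),
                    class = "ligand_pose")
  cls <- classify_pose(pose, fx$receptor, fx$site)
  expect_false(cls$productive)
  expect_equal(cls$bond_kind, "none")
})

test_that("probe atom choice (backbone H vs N) changes the geometry", {
  fx <- make_site_fixture(2.0, 4.4, 1.0)
  site_h <- active_site("A:130:OG", c("A:60", "A:131"), probe = "H")
  site_n <- active_site("A:130:OG", c("A:60", "A:131"), probe = "N")
  cls_h <- classify_pose(fx$pose, fx$receptor, site_h)
  cls_n <- classify_pose(fx$pose, fx$receptor, site_n)
  expect_equal(cls_h$probe, "H")
  expect_equal(cls_n$probe, "N")
  expect_gt(cls_n$d_oxy1, cls_h$d_oxy1)  # N sits 1.01 A behind H
  expect_true(cls_h$productive)
  expect_false(cls_n$productive)
})

test_that("unresolvable site atoms raise an error", {
  fx <- make_site_fixture(3, 3, 3)
  bad <- active_site("A:999:OG", c("A:60", "A:131"))
  expect_error(classify_pose(fx$pose, fx$receptor, bad), "unresolvable")
  expect_error(active_site("A:130:OG", "A:60"), "exactly two")
})

test_that("summaries count, partition and permute correctly", {
  set.seed(13)
  dists <- c(rep(2, 3), rep(6, 7)) # 3 productive of 10
  fixtures <- lapply(dists, function(d) make_site_fixture(d, 2, 2))
  cls <- do.call(rbind, lapply(seq_along(fixtures), function(i) {
    r <- classify_pose(fixtures[[i]]$pose, fixtures[[i]]$receptor,
                       fixtures[[i]]$site)
    r$ligand <- sprintf("lig_%d", i)
    r
  }))
  s <- summarize_poses(cls)
  expect_equal(s$pct_productive, 30)
  expect_equal(s$pct_productive + s$pct_nonproductive, 100)
  expect_length(s$d_ser, 10)
  # permutation invariance
  s2 <- summarize_poses(cls[sample(nrow(cls)), ])
  expect_equal(s2$pct_productive, s$pct_productive)
  # per-class summary and urethane preference
  meta <- data.frame(id = sprintf("lig_%d", 1:10),
                     isocyanate_class = rep(c("HDI", "MDI"), 5),
                     has_ester = rep(c(TRUE, FALSE), 5))
  s3 <- summarize_poses(cls, meta)
  expect_setequal(s3$by_class$class, c("HDI", "MDI"))
  agg <- s3$by_class$pct_productive[s3$by_class$class == "HDI"]
  expect_equal(agg, 100 * 2 / 5) # ligands 1,3,5,7,9: two productive
  expect_equal(s3$pct_urethane_nac, 100) # fixture bonds are urethanes
  expect_error(summarize_poses(cls, meta[1:3, ]), "missing from metadata")
})
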