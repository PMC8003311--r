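# Nine-point surveys and the composite index.

test_that("survey assembly enforces the nine-role grid", {
  pts <- data.frame(role = survey_roles(), clip_ref = survey_roles(),
                    aci = 1:9, ndsi = rep(0.5, 9), stringsAsFactors = FALSE)
  expect_s3_class(area_survey("ok", pts), "area_survey")

  expect_error(area_survey("x", pts[-9, ]), "missing role core in area x")
  expect_error(area_survey("x", pts[-3, ]), "missing role edge3")
  dup <- pts; dup$role[2] <- "edge1"
  expect_error(area_survey("x", dup), "missing role edge2")
  bad <- pts; bad$ndsi[1] <- 1.5
  expect_error(area_survey("x", bad), "NDSI values")
  neg <- pts; neg$aci[1] <- -1
  expect_error(area_survey("x", neg), "non-negative")
})

test_that("complexity balance follows its defining ratio", {
  expect_equal(complexity_balance(
    survey_from_values(c(rep(12, 8), 8), rep(0.2, 9))), 1.5)
  expect_equal(complexity_balance(
    survey_from_values(c(rep(6, 8), 12), rep(0.2, 9))), 0.5)
  expect_identical(complexity_balance(
    survey_from_values(rep(3.7, 9), rep(0.2, 9))), 1)
  expect_error(complexity_balance(
    survey_from_values(c(rep(2, 8), 0), rep(0.2, 9))), "silent core")
})

test_that("the ACI range spans all nine points and ignores labels", {
  expect_identical(aci_range(survey_from_values(rep(4, 9), rep(0, 9))), 0)
  vals <- c(0.75, 0.80, 1.40, 0.90, 1.00, 0.60, 1.10, 0.95, 1.20)
  expect_equal(aci_range(survey_from_values(vals, rep(0, 9))), 0.80)
  set.seed(41)
  for (i in 1:10) {
    perm <- sample(vals)
    expect_equal(aci_range(survey_from_values(perm, rep(0, 9))),
                 aci_range(survey_from_values(vals, rep(0, 9))))
  }
})

test_that("the disturbance sign is the sign of the mean NDSI", {
  expect_identical(anthropogenic_disturbance(
    survey_from_values(1:9, rep(0.4, 9))), 1)
  expect_identical(anthropogenic_disturbance(
    survey_from_values(1:9, rep(-0.2, 9))), -1)
  balanced <- c(rep(0.5, 4), rep(-0.5, 4), 0)
  expect_identical(anthropogenic_disturbance(
    survey_from_values(1:9, balanced)), 0)
})

test_that("CUQI composes its three parts and is recomputable bit-for-bit", {
  sc <- cuqi(survey_from_values(c(rep(1.2, 8), 1.0), rep(0.4, 9)))
  expect_equal(sc$cb, 1.2)
  expect_equal(sc$rg_aci, 0.2)
  expect_identical(sc$ad, 1)
  expect_identical(sc$cuqi, sc$ad * (sc$rg_aci * sc$cb))
  expect_equal(sc$cuqi, 0.24, tolerance = 1e-12)
})

test_that("zero complexity range annihilates CUQI regardless of the rest", {
  sc <- cuqi(survey_from_values(rep(5, 9), rep(-0.8, 9)))
  expect_identical(sc$cuqi, 0)
  expect_identical(sc$ad, -1)
})

test_that("sign(CUQI) equals AD whenever the range is positive", {
  set.seed(42)
  for (i in 1:50) {
    aci_vals <- runif(9, 0.1, 10)
    ndsi_vals <- runif(9, -1, 1)
    sc <- cuqi(survey_from_values(aci_vals, ndsi_vals))
    if (sc$rg_aci > 0) expect_identical(sign(sc$cuqi), sc$ad)
  }
})

test_that("CUQI is invariant to relabeling among the eight edges", {
  set.seed(43)
  aci_vals <- runif(9, 0.5, 5)
  ndsi_vals <- runif(9, -1, 1)
  base <- cuqi(survey_from_values(aci_vals, ndsi_vals))
  for (i in 1:10) {
    p <- sample(8)
    sc <- cuqi(survey_from_values(c(aci_vals[p], aci_vals[9]),
                                  c(ndsi_vals[p], ndsi_vals[9])))
    expect_identical(sc$cuqi, base$cuqi)
  }
})

test_that("ranking is by descending CUQI with a lexicographic tie-break", {
  mk <- function(name, edge_aci, core_aci, nd) {
    cuqi(survey_from_values(c(rep(edge_aci, 8), core_aci), rep(nd, 9), name))
  }
  a <- mk("A", 4, 2, 0.5)    # cb 2, rg 2, cuqi 4
  b <- mk("B", 2.5, 2, 0.5)  # cuqi ~0.625
  c_ <- mk("C", 2.5, 3, -0.5)  # negative
  r <- rank_areas(list(c_, b, a))
  expect_identical(r$area_name, c("A", "B", "C"))
  expect_identical(r$rank, 1:3)

  tie1 <- mk("B", 3, 2, 0.5); tie2 <- mk("A", 3, 2, 0.5)
  expect_identical(rank_areas(list(tie1, tie2))$area_name, c("A", "B"))
  expect_identical(rank_areas(list(tie2, tie1))$area_name, c("A", "B"))
  expect_error(rank_areas(list(a, mk("A", 1, 1, 0))), "duplicate area_name")
  expect_error(rank_areas(list()), "at least one")
})

test_that("surveys build end-to-end from clips and manifests", {
  scn <- scenario(duration_s = 6, seed = 77)
  dir <- withr::local_tempdir()
  out <- render_survey(scn, "parkA", dir)
  surveys <- surveys_from_manifest(out$manifest)
  expect_named(surveys, "parkA")
  sv <- surveys$parkA
  expect_identical(sort(sv$points$role), sort(survey_roles()))
  expect_true(all(sv$points$aci >= 0))
  expect_true(all(abs(sv$points$ndsi) <= 1))

  direct <- survey_from_clips("parkA", simulate_survey(scn)$clips)
  expect_equal(sv$points$aci, direct$points$aci, tolerance = 1e-5)
  expect_equal(cuqi(sv)$cuqi, cuqi(direct)$cuqi, tolerance = 1e-4)

  man <- utils::read.csv(out$manifest, stringsAsFactors = FALSE)
  utils::write.csv(man[man$role != "core", ], out$manifest, row.names = FALSE)
  expect_error(surveys_from_manifest(out$manifest), "missing role core")
})

test_that("unequal recording lengths are reconciled before scoring", {
  scn <- scenario(duration_s = 6, seed = 78)
  clips <- simulate_survey(scn)$clips
  long <- scenario(duration_s = 7, seed = 78)
  clips$core <- simulate_point(long, "core")
  sv <- survey_from_clips("mixed_len", clips)
  expect_s3_class(sv, "area_survey")  # truncation reconciles the core clip
})
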