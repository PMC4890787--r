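test_that("line-origin posteriors recover the true transmission at zero noise", {
  cross <- simulate_cross(mb_cross_config(n_f2 = 120, seed = 61,
                                          n_background_chrom = 0))
  tracks <- infer_line_origin(cross$genotypes, cross$pedigree, cross$map,
                              error_rate = 0)
  truth <- cross$true_origin
  cls_true <- paste0(truth$paternal, truth$maternal)
  cls_true[cls_true == "LH"] <- "HL"
  dim(cls_true) <- dim(truth$paternal)
  idx <- match(cross$map$cM, tracks$grid_cM)
  states <- c("HH", "HL", "LL")
  cls_post <- apply(tracks$prob[, idx, ], c(1, 2),
                    function(v) states[which.max(v)])
  expect_equal(mean(cls_post == cls_true), 1)
  ## posteriors are proper distributions everywhere
  expect_true(all(abs(apply(tracks$prob, c(1, 2), sum) - 1) < 1e-8))
})

test_that("uninformative markers leave the posterior at the F2 prior", {
  ## both founder lines fixed for the same allele at every marker
  ids <- c("HB_M", "HB_F", "HQLA_M", "HQLA_F", "F2_1", "F2_2")
  calls <- matrix(2L, 6, 5, dimnames = list(ids, sprintf("M%d", 1:5)))
  gm <- genotype_matrix(calls, data.frame(id = colnames(calls), chrom = "c",
                                          bp = (1:5) * 1e5))
  ped <- data.frame(id = ids, sire = NA, dam = NA, sex = "M",
                    generation = c(rep("F0", 4), "F2", "F2"),
                    line = c("HB", "HB", "HQLA", "HQLA", NA, NA))
  map <- data.frame(marker = colnames(calls), chrom = "c", bp = (1:5) * 1e5,
                    cM = 0:4)
  tracks <- infer_line_origin(gm, ped, map, error_rate = 0)
  expect_true(all(abs(tracks$prob[, , "HH"] - 0.25) < 1e-9))
  expect_true(all(abs(tracks$prob[, , "HL"] - 0.50) < 1e-9))
})

test_that("an individual missing from the pedigree is a lineage error", {
  cross <- simulate_cross(mb_cross_config(n_f2 = 20, seed = 62,
                                          n_background_chrom = 0))
  expect_error(infer_line_origin(cross$genotypes, cross$pedigree, cross$map,
                                 individuals = c("F2_0001", "ghost")),
               "absent from pedigree")
})

test_that("the linkage peak localises a dominant locus at 5 cM", {
  cross <- simulate_cross(mb_cross_config(n_f2 = 500, seed = 63,
                                          n_background_chrom = 0))
  tracks <- infer_line_origin(cross$genotypes, cross$pedigree, cross$map,
                              error_rate = 0)
  fs <- linkage_scan(tracks, cross$phenotypes)
  expect_true(abs(fs$grid_cM[which.max(fs$F)] - 5) <= 1)
})

test_that("a missing origin class drops the test to 1 df with a notice", {
  set.seed(64)
  n <- 60
  ids <- sprintf("I%02d", seq_len(n))
  ## only HH and HL present (no LL individuals anywhere)
  prob <- array(0, c(n, 5, 3), dimnames = list(ids, NULL, c("HH", "HL", "LL")))
  hh <- stats::rbinom(n, 1, 0.5)
  for (k in 1:5) {
    prob[, k, "HH"] <- hh
    prob[, k, "HL"] <- 1 - hh
  }
  tracks <- structure(list(prob = prob, grid_cM = 0:4, grid_bp = (0:4) * 1e5,
                           individuals = ids,
                           map = data.frame(marker = sprintf("M%d", 1:5),
                                            chrom = "c", bp = (0:4) * 1e5,
                                            cM = 0:4),
                           chrom = "c"), class = "line_origin_tracks")
  ph <- data.frame(id = ids, mb_week10 = stats::rbinom(n, 1, 0.5),
                   mb_at_birth = 0L)
  expect_message(fs <- linkage_scan(tracks, ph), "1-df")
  expect_true(all(fs$df1 == 1L))
})

test_that("randomization threshold quantile edges and errors behave", {
  cross <- simulate_cross(mb_cross_config(n_f2 = 80, seed = 65,
                                          n_background_chrom = 0))
  tracks <- infer_line_origin(cross$genotypes, cross$pedigree, cross$map,
                              error_rate = 0)
  expect_error(randomization_threshold(tracks, cross$phenotypes, n_perm = 50),
               "n_perm")
  ph_const <- cross$phenotypes
  ph_const$mb_week10 <- 1L
  expect_error(randomization_threshold(tracks, ph_const, n_perm = 100),
               "constant phenotype")
  thr1 <- randomization_threshold(tracks, cross$phenotypes, n_perm = 100,
                                  alpha = 1, seed = 9)
  expect_equal(as.numeric(thr1), min(attr(thr1, "max_f")))
  ## reproducible under a fixed seed
  thr_a <- randomization_threshold(tracks, cross$phenotypes, n_perm = 100,
                                   seed = 4)
  thr_b <- randomization_threshold(tracks, cross$phenotypes, n_perm = 100,
                                   seed = 4)
  expect_identical(as.numeric(thr_a), as.numeric(thr_b))
})

test_that("shared-IBD logic matches an exhaustive position scan", {
  ## trivial case: one affected HH everywhere, one unaffected LL everywhere
  mk_tracks <- function(cls) {
    n <- nrow(cls); g <- ncol(cls)
    prob <- array(0, c(n, g, 3),
                  dimnames = list(rownames(cls), NULL, c("HH", "HL", "LL")))
    for (i in seq_len(n)) for (k in seq_len(g)) prob[i, k, cls[i, k]] <- 1
    structure(list(prob = prob, grid_cM = seq_len(g) - 1,
                   grid_bp = (seq_len(g) - 1) * 1e5 + 1e5,
                   individuals = rownames(cls),
                   map = data.frame(marker = sprintf("M%02d", seq_len(g)),
                                    chrom = "c",
                                    bp = (seq_len(g) - 1) * 1e5 + 1e5,
                                    cM = seq_len(g) - 1),
                   chrom = "c"), class = "line_origin_tracks")
  }
  cls <- rbind(mb1 = rep("HH", 10), wt1 = rep("LL", 10))
  ph <- data.frame(id = c("mb1", "wt1"), mb_week10 = c(1L, 0L),
                   mb_at_birth = 0L)
  iv <- shared_ibd_interval(mk_tracks(cls), ph)
  expect_equal(iv$n_positions, 10L)
  expect_equal(c(iv$start_bp, iv$end_bp), c(1e5, 10e5))

  ## four recombinants flanking a known 3-position window
  cls2 <- rbind(
    mb1 = c(rep("LL", 3), rep("HL", 7)),          # carrier from position 4
    mb2 = c(rep("HL", 6), rep("LL", 4)),          # carrier through position 6
    wt1 = c(rep("HL", 3), rep("LL", 7)),          # carrier through position 3
    wt2 = c(rep("LL", 6), rep("HH", 4))           # carrier from position 7
  )
  rownames(cls2) <- c("mb1", "mb2", "wt1", "wt2")
  ph2 <- data.frame(id = rownames(cls2), mb_week10 = c(1L, 1L, 0L, 0L),
                    mb_at_birth = 0L)
  tr2 <- mk_tracks(cls2)
  iv2 <- shared_ibd_interval(tr2, ph2)
  ## brute-force oracle over every grid position
  qual <- vapply(seq_len(10), function(k) {
    car <- cls2[, k] %in% c("HH", "HL")
    all(car[1:2]) && !any(car[3:4])
  }, logical(1))
  expect_equal(which(qual), 4:6)
  expect_equal(iv2$n_positions, 3L)
  expect_equal(iv2$grid_cM, c(3, 5))
  expect_equal(iv2$boundary_individuals$left, c("mb1", "wt1"))
  expect_equal(iv2$boundary_individuals$right, c("mb2", "wt2"))

  ## phenocopy: an affected individual with LL at the locus empties the result
  cls3 <- rbind(mb1 = rep("HL", 10), mb2 = rep("LL", 10),
                wt1 = rep("LL", 10))
  ph3 <- data.frame(id = rownames(cls3), mb_week10 = c(1L, 1L, 0L),
                    mb_at_birth = 0L)
  expect_message(iv3 <- shared_ibd_interval(mk_tracks(cls3), ph3), "empty")
  expect_true(iv3$empty)
  expect_error(shared_ibd_interval(mk_tracks(cls3),
                                   transform(ph3, mb_week10 = 0L)),
               "no affected")
})

test_that("the shared-IBD interval contains the causal locus and shrinks with n", {
  width_of <- function(n, seed) {
    cross <- simulate_cross(mb_cross_config(n_f2 = n, seed = seed,
                                            n_background_chrom = 0))
    tracks <- infer_line_origin(cross$genotypes, cross$pedigree, cross$map,
                                error_rate = 0)
    iv <- shared_ibd_interval(tracks, cross$phenotypes)
    expect_false(iv$empty)
    expect_true(iv$start_bp <= 550000 && iv$end_bp >= 550000)
    iv$end_bp - iv$start_bp
  }
  w_small <- vapply(1:3, function(s) width_of(60, 70 + s), numeric(1))
  w_large <- vapply(1:3, function(s) width_of(360, 80 + s), numeric(1))
  expect_lte(mean(w_large), mean(w_small))
})
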