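pair0 <- generate_clamshell(clamshell_spec(theta = 25, noise_sigma = 0,
                                           seed = 4))

test_that("a structure superposed on itself is exact for any selection", {
  s <- pair0$closed
  sup <- superpose_on_selection(s, s, pair0$scheme$subdomain2)
  expect_lt(sup$rmsd_selection, 1e-9)
  expect_lt(sup$rmsd_global, 1e-9)
  expect_identical(sup$n_selection, length(pair0$scheme$subdomain2))
})

test_that("anchored selection rmsd never exceeds the global rmsd on open/closed pairs", {
  for (seed in 1:5) {
    pair <- generate_clamshell(clamshell_spec(theta = 20, noise_sigma = 0.3,
                                              seed = seed))
    sup <- superpose_on_selection(pair$open, pair$closed,
                                  pair$scheme$subdomain2)
    expect_lte(sup$rmsd_selection, sup$rmsd_global + 1e-12)
  }
})

test_that("superposition needs at least three selected pairs", {
  expect_error(superpose_on_selection(pair0$open, pair0$closed,
                                      selection = c(1L, 2L)),
               "fewer than 3")
})

test_that("displacement profile equals the analytic field at sigma = 0", {
  prof <- displacement_profile(pair0$open, pair0$closed, pair0$scheme)
  truth <- pair0$truth$displacement
  m <- merge(as.data.frame(prof), truth, by = "resno",
             suffixes = c("_est", "_true"))
  expect_identical(nrow(m), nrow(truth))
  expect_lt(max(abs(m$displacement_est - m$displacement_true)), 1e-6)
  # identical structures give an all-zero profile
  prof0 <- displacement_profile(pair0$closed, pair0$closed, pair0$scheme)
  expect_lt(max(prof0$displacement), 1e-9)
})

test_that("region summaries report max/argmax/mean and missing counts", {
  prof <- displacement_profile(pair0$open, pair0$closed, pair0$scheme)
  reg <- summarize_regions(prof, pair0$scheme)
  truth <- pair0$truth$displacement
  expect_equal(reg$max_displacement[reg$region == "lobe1"],
               max(truth$displacement), tolerance = 1e-6)
  expect_identical(reg$argmax_resno[reg$region == "lobe1"],
                   truth$resno[which.max(truth$displacement)])
  expect_gte(reg$max_displacement[1], reg$mean_displacement[1])
  # all-zero profile -> zero maxima
  prof0 <- displacement_profile(pair0$closed, pair0$closed, pair0$scheme)
  expect_lt(max(summarize_regions(prof0, pair0$scheme)$max_displacement), 1e-9)
  # a region absent from the correspondence is flagged, not fatal
  sch <- subdomain_scheme("gap", subdomain1 = c(1:80, 900:910),
                          subdomain2 = pair0$scheme$subdomain2,
                          regions = list(ghost = 900:910))
  expect_warning(summarize_regions(prof, sch), "ghost")
})

test_that("hinge detection is quiet on flat profiles and localises a true hinge", {
  flat <- data.frame(resno = 1:50, displacement = rep(0.1, 50))
  expect_identical(nrow(detect_hinges(flat)), 0L)
  # single-hinge synthetic: hinge loop at residues n1+1 .. n1+4
  for (seed in 1:5) {
    pair <- generate_clamshell(clamshell_spec(theta = 25, noise_sigma = 0.2,
                                              seed = seed))
    prof <- displacement_profile(pair$open, pair$closed, pair$scheme)
    calls <- detect_hinges(prof, pair$scheme)
    expect_gt(nrow(calls), 0)
    best <- calls[which.max(calls$score), ]
    lo <- min(pair$truth$hinge_range); hi <- max(pair$truth$hinge_range)
    expect_lte(max(0, lo - best$end_resno, best$start_resno - hi), 2)
    expect_true(all(calls$score > 1))
  }
})

test_that("opening transform recovers angle and axis from noiseless synthetic data", {
  screw <- opening_transform(pair0$open, pair0$closed, pair0$scheme)
  expect_equal(screw$angle_deg, 25, tolerance = 0.1)
  expect_gte(sum(screw$axis_direction * pair0$truth$axis_direction), 0.999)
  # the annotated hinge is the scheme element nearest the recovered axis
  hd <- screw$hinge_axis_distances
  expect_identical(hd$hinge[1], "h1")
  expect_lt(hd$min_axis_distance[1], 1.0)
  # identical structures: no rotation
  s0 <- opening_transform(pair0$closed, pair0$closed, pair0$scheme)
  expect_lt(s0$angle_deg, 0.1)
})

test_that("hetero displacement matches 2 r sin(theta/2) under the anchored fit", {
  d <- hetero_displacement(pair0$open, pair0$closed, "ZN",
                           scheme = pair0$scheme)
  expect_equal(d, pair0$truth$metal_displacement, tolerance = 1e-6)
  expect_lt(hetero_displacement(pair0$closed, pair0$closed, "ZN",
                                scheme = pair0$scheme), 1e-9)
  # subdomain-1 maximum bounds the interface-metal motion
  prof <- displacement_profile(pair0$open, pair0$closed, pair0$scheme)
  expect_gte(max(prof$displacement[prof$resno %in% pair0$scheme$subdomain1]), d)
})

test_that("hetero selector errors on ambiguity", {
  dup <- pair0$open
  extra <- dup$atom[dup$atom$resid == "ZN", ]
  extra$eleno <- max(dup$atom$eleno) + 1L
  extra$resno <- extra$resno + 1L
  dup$atom <- rbind(dup$atom, extra)
  expect_error(hetero_displacement(dup, pair0$closed, "ZN",
                                   scheme = pair0$scheme), "disambiguate")
})

test_that("pairwise rmsd matrix is symmetric with a zero diagonal", {
  specs <- list(clamshell_spec(theta = 0, noise_sigma = 0.2, seed = 1),
                clamshell_spec(theta = 10, noise_sigma = 0.2, seed = 2),
                clamshell_spec(theta = 25, noise_sigma = 0.2, seed = 3))
  confs <- lapply(specs, function(sp) generate_clamshell(sp)$open)
  names(confs) <- paste0("conf", 1:3)
  m <- pairwise_rmsd_matrix(confs)
  expect_identical(m$rmsd, t(m$rmsd))
  expect_identical(unname(diag(m$rmsd)), rep(0, 3))
  expect_true(all(m$rmsd[upper.tri(m$rmsd)] > 0))
  # duplicated structure: off-diagonal zero
  m0 <- pairwise_rmsd_matrix(list(a = confs[[1]], b = confs[[1]]))
  expect_lt(m0$rmsd[1, 2], 1e-9)
  expect_identical(m0$n[1, 2], nrow(extract_calpha_trace(confs[[1]], "A")))
})

test_that("the domain_motion fit object exposes the analysis through methods", {
  fit <- domain_motion(pair0$open, pair0$closed, pair0$scheme)
  expect_s3_class(fit, "domain_motion")
  co <- coef(fit)
  expect_equal(unname(co["angle_deg"]), 25, tolerance = 0.1)
  res <- residuals(fit)
  expect_identical(length(res), nrow(fit$profile))
  expect_true(all(res >= 0))
  expect_output(print(fit), "opening: 25")
  expect_output(print(summary(fit)), "Region motion summary")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # nACE is the default scheme
  expect_identical(formals(domain_motion)$scheme, quote(nace_scheme()))
})

test_that("the built-in nACE scheme carries the published partition", {
  sch <- nace_scheme()
  expect_identical(sch$subdomain1, c(11:97, 272:417, 507:566))
  expect_identical(sch$subdomain2, c(98:271, 418:506, 567:601))
  expect_identical(sch$regions$region1, 272:378)
  expect_identical(sch$regions$region4, 552:566)
  expect_identical(sch$hinges$h6, 548:551)
  expect_identical(sch$hinges$h7, 567L)
  expect_identical(sch$lid, 14:100)
  expect_length(intersect(sch$subdomain1, sch$subdomain2), 0)
  expect_error(subdomain_scheme("bad", 1:10, 11:20,
                                regions = list(r = 15:16)),
               "outside subdomain 1")
})
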