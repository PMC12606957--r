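test_that("compartment table carries the endolymph/perilymph sodium contrast", {
  tab <- compartment_table()
  expect_equal(tab$sodium_mM[tab$label == "endolymph"], 1.3)
  expect_equal(tab$sodium_mM[tab$label == "perilymph"], 145)
  expect_true(all(tab$t2star_ms <= tab$t2_ms))
  expect_true(all(tab$t2_ms <= tab$t1_ms))
})

test_that("default structure volumes fall in the observers' printed ranges", {
  ph <- build_phantom(phantom_spec())
  v <- phantom_mask_volumes(ph)
  expect_gte(v[["cochlea_right"]], 63)
  expect_lte(v[["cochlea_right"]], 110)
  expect_gte(v[["vestibule_right"]], 31)
  expect_lte(v[["vestibule_right"]], 59)
  expect_equal(v[["cochlea_left"]], v[["cochlea_right"]])
})

test_that("phantom construction is mirror-symmetric and monotone in hydrops", {
  # equal hydrops fractions give exactly mirror-symmetric concentration maps
  ph <- build_phantom(phantom_spec(grid_shape = 64, ear_offset_mm = 20,
                                   hydrops_fraction = c(0.4, 0.4)))
  cm <- ph$concentration_map
  n <- dim(cm)[1]
  mir <- cm; mir[1, , ] <- 0; mir[2:n, , ] <- cm[n:2, , ]
  expect_equal(max(abs(cm - mir)), 0)

  # zero hydrops both sides: summed concentration equal between ears
  ph0 <- build_phantom(phantom_spec(grid_shape = 64, ear_offset_mm = 20,
                                    hydrops_fraction = c(0, 0)))
  left <- ph0$masks$cochlea_left | ph0$masks$vestibule_left
  right <- ph0$masks$cochlea_right | ph0$masks$vestibule_right
  expect_equal(sum(ph0$concentration_map[left]),
               sum(ph0$concentration_map[right]))

  # strong left hydrops lowers the left mean concentration
  ph2 <- build_phantom(phantom_spec(grid_shape = 64, ear_offset_mm = 20,
                                    hydrops_fraction = c(0.9, 0.1)))
  l2 <- ph2$masks$cochlea_left | ph2$masks$vestibule_left
  r2 <- ph2$masks$cochlea_right | ph2$masks$vestibule_right
  expect_lt(mean(ph2$concentration_map[l2]),
            mean(ph2$concentration_map[r2]))
})

test_that("every voxel's concentration is a compartment table entry", {
  ph <- build_phantom(phantom_spec(grid_shape = 64, ear_offset_mm = 20))
  expect_true(all(ph$concentration_map %in% compartment_table()$sodium_mM))
  expect_true(all(abs(ph$offres_map) <= ph$spec$b0_amplitude_hz))
})

test_that("hydrops series conserves fluid volume and mixes monotonically", {
  spec <- phantom_spec(grid_shape = 64, ear_offset_mm = 20)
  series <- hydrops_series(spec, c(0, 0.5, 1))
  expect_length(series, 3)
  inner <- function(p) p$masks$cochlea_left | p$masks$vestibule_left
  means <- vapply(series, function(p) mean(p$concentration_map[inner(p)]),
                  numeric(1))
  expect_true(all(diff(means) < 0))
  counts <- vapply(series, function(p) sum(inner(p)), numeric(1))
  expect_true(all(counts == counts[1]))
  # full replacement: inner-ear fluid entirely endolymph
  endo_code <- compartment_table()$code[
    compartment_table()$label == "endolymph"]
  p1 <- series[[3]]
  expect_true(all(p1$label_map[inner(p1)] == endo_code))
  # determinism: identical spec and seed give bit-identical phantoms
  expect_identical(hydrops_series(spec, 0.3)[[1]]$concentration_map,
                   hydrops_series(spec, 0.3)[[1]]$concentration_map)
  expect_error(hydrops_series(spec, numeric(0)), "non-empty")
})

test_that("ill-fitting geometry is rejected with a parameter error", {
  expect_error(phantom_spec(grid_shape = 32, voxel_size_mm = 1),
               "does not cover both ears")
  expect_error(phantom_spec(hydrops_fraction = c(1.2, 0)))
})
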