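# APP buffers, Forest Code balance, patch classification, attribution,
# protected-area flags and the land-category breakdown.

test_that("APP strip area matches the analytic buffer area", {
  # one straight 10 km stream, 30 m half-width: strip = 60 ha (+ end caps)
  streams <- data.frame(stream_id = "S01",
                        x = seq(0, 10000, by = 1000), y = 5000)
  app <- derive_app_zones(streams, rule_config(app_buffer_m = 30))
  a <- app_zone_area_ha(app, cell_m = 4)
  analytic <- (10000 * 60 + pi * 30^2) / 1e4
  expect_equal(a, analytic, tolerance = 0.01)

  # empty stream set: empty APP geometry
  empty <- derive_app_zones(streams[0, ], rule_config())
  expect_equal(app_zone_area_ha(empty), 0)
  expect_false(enforcelens:::rect_intersects_app(c(0, 0, 10, 10), empty))

  # two crossing streams: union area does not double count
  cross <- rbind(streams,
                 data.frame(stream_id = "S02", x = 5000,
                            y = seq(0, 10000, by = 1000)))
  app2 <- derive_app_zones(cross, rule_config(app_buffer_m = 30))
  a2 <- app_zone_area_ha(app2, cell_m = 4)
  expect_lt(a2, 2 * analytic)
  expect_gt(a2, 1.9 * analytic)
  expect_error(derive_app_zones(streams,
                                list(app_buffer_m = -5)), "buffer")
})

test_that("Forest Code balance arithmetic follows the deficit definition", {
  side <- 1000                       # 100 ha square holding
  h <- square_holding(side)
  g <- grid_spec(c(0, 0), 10, 100, 100)
  make_native <- function(frac) {
    m <- matrix(0, 100, 100)
    m[seq_len(round(frac * 10000))] <- 1
    m
  }
  # 85 ha native of 100 ha: compliant, zero deficit
  b85 <- compute_fc_balance(h, make_native(0.85), g, rule_config())
  expect_equal(b85$deficit_ha, 0)
  expect_true(b85$compliant)
  # 70 ha native, requirement 0.80: 10 ha deficit
  b70 <- compute_fc_balance(h, make_native(0.70), g, rule_config())
  expect_equal(b70$native_fraction, 0.70)
  expect_equal(b70$deficit_ha, 10, tolerance = 1e-9)
  expect_false(b70$compliant)
  # fully native holding saturates
  b100 <- compute_fc_balance(h, make_native(1), g, rule_config())
  expect_equal(b100$native_fraction, 1)
  expect_true(b100$compliant)
  # deficit is monotone non-increasing in native fraction
  fr <- seq(0.5, 1, by = 0.05)
  defs <- vapply(fr, function(f)
    compute_fc_balance(h, make_native(f), g, rule_config())$deficit_ha, 0)
  expect_true(all(diff(defs) <= 1e-9))
  expect_true(all(defs[fr >= 0.8] == 0))
})

test_that("patch classification applies MMU, APP and LR-deficit rules in order", {
  h <- square_holding(2000)          # 400 ha holding
  stream <- data.frame(stream_id = "S01", x = c(0, 2000), y = 500)
  app <- derive_app_zones(stream, rule_config(app_buffer_m = 30))
  rules <- rule_config()
  bal_ok <- balance_row(h, compliant = TRUE)
  bal_bad <- balance_row(h, compliant = FALSE)

  p_small <- patch_row(1000, 1500, 5, id = "D1")       # 5 ha anywhere
  p_app <- patch_row(1000, 520, 10, id = "D2")         # 10 ha on the stream
  p_clear <- patch_row(1200, 1500, 10, id = "D3")      # 10 ha away from APP

  out <- classify_patches(rbind(p_small, p_app, p_clear), h, bal_ok, app, rules)
  expect_equal(out$label, c("below_mmu", "potentially_illegal",
                            "presumed_legal"))
  expect_equal(out$reason, c("none", "riparian_app", "none"))

  # same patches on a non-compliant holding: LR deficit fires, APP precedes
  out2 <- classify_patches(rbind(p_app, p_clear), h, bal_bad, app, rules)
  expect_equal(out2$label, rep("potentially_illegal", 2))
  expect_equal(out2$reason, c("riparian_app", "lr_deficit"))
  # a 5 ha patch is below MMU regardless of holding compliance
  out3 <- classify_patches(p_small, h, bal_bad, app, rules)
  expect_equal(out3$label, "below_mmu")
})

test_that("patches straddling holdings go to the largest overlap", {
  h1 <- square_holding(1000, c(0, 0), id = "HA")
  h2 <- square_holding(1000, c(1000, 0), id = "HB")
  h <- rbind(h1, h2)
  attr(h, "polygons") <- c(attr(h1, "polygons"), attr(h2, "polygons"))
  bal <- balance_row(h, compliant = TRUE)
  app <- derive_app_zones(data.frame(stream_id = character(0),
                                     x = numeric(0), y = numeric(0)))
  # 70% of the patch lies in HB
  p <- patch_row(1100, 500, 25, id = "DX")
  out <- classify_patches(p, h, bal, app, rule_config())
  expect_equal(out$holding_id, "HB")
})

test_that("notice attribution respects containment and temporal precedence", {
  h <- square_holding(1000)
  patches <- data.frame(holding_id = "H0001", year = 2013, area_ha = 10)
  notices <- data.frame(record_id = c("N1", "N2", "N3"),
                        year = c(2015, 2012, 2015),
                        x = c(500, 500, 5000), y = c(500, 500, 5000),
                        stringsAsFactors = FALSE)
  att <- attribute_notices(notices, patches, h)
  expect_equal(att$holding_id, c("H0001", "H0001", NA))
  expect_equal(att$deforestation_related, c(TRUE, FALSE, FALSE))
  # below-MMU deforestation does not create a temporal link
  att2 <- attribute_notices(notices,
                            transform(patches, area_ha = 3), h)
  expect_equal(att2$deforestation_related, c(FALSE, FALSE, FALSE))
})

test_that("protected-area overlap flag uses a strict 25% threshold", {
  h <- square_holding(1000)
  pa30 <- data.frame(pa_id = "PA1", pa_class = "indigenous_land",
                     xmin = 0, ymin = 0, xmax = 300, ymax = 1000)
  f30 <- protected_overlap_flags(h, pa30, rule_config())
  expect_equal(f30$overlap_fraction, 0.30)
  expect_true(f30$flagged)
  pa25 <- transform(pa30, xmax = 250)
  f25 <- protected_overlap_flags(h, pa25, rule_config())
  expect_equal(f25$overlap_fraction, 0.25)
  expect_false(f25$flagged)    # strictly greater than the threshold
  pa_far <- transform(pa30, xmin = 5000, xmax = 6000)
  f0 <- protected_overlap_flags(h, pa_far, rule_config())
  expect_equal(f0$overlap_fraction, 0)
  expect_false(f0$flagged)
  # flag count is monotone in the threshold
  fr <- seq(0.05, 0.95, by = 0.1)
  flags <- vapply(fr, function(t)
    protected_overlap_flags(h, pa30,
                            rule_config(overlap_threshold = t))$flagged, TRUE)
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("land-category breakdown conserves area and applies precedence", {
  h <- square_holding(2000)
  # patch fully inside an indigenous land
  pa <- data.frame(pa_id = "PA1", pa_class = "indigenous_land",
                   xmin = 0, ymin = 0, xmax = 2000, ymax = 2000)
  p <- patch_row(1000, 1000, 12, year = 2011)
  bd <- land_category_breakdown(p, h, pa)
  expect_equal(bd$indigenous_land, 12)
  expect_equal(bd$landholding, 0)
  expect_equal(bd$total_ha, 12)
  # patch half in a CU that overlaps the holding: CU wins on the overlap
  pa2 <- data.frame(pa_id = "PA2", pa_class = "conservation_unit",
                    xmin = 0, ymin = 0, xmax = 1000, ymax = 2000)
  p2 <- patch_row(1000, 1000, 16, year = 2011, aspect = 1)  # 400 m square
  bd2 <- land_category_breakdown(p2, h, pa2, n_sample = 80L)
  expect_equal(bd2$conservation_unit, 8, tolerance = 0.02)
  expect_equal(bd2$landholding, 8, tolerance = 0.02)
  expect_equal(bd2$total_ha, 16, tolerance = 1e-9)
  # per-year totals conserve total patch area
  cfg <- small_cfg(seed = 17)
  ls <- generate_landscape(cfg)
  bd3 <- land_category_breakdown(ls$patches, ls$holdings,
                                 ls$protected_areas)
  per_year <- tapply(ls$patches$area_ha, ls$patches$year, sum)
  expect_equal(bd3$total_ha, as.numeric(per_year), tolerance = 0.005)
})

test_that("illegality-enforcement series hits 100% and 0% at the extremes", {
  labels <- data.frame(
    patch_id = c("D1", "D2"), year = c(2012, 2013),
    holding_id = c("H1", "H2"),
    label = "potentially_illegal", reason = "riparian_app",
    area_ha = c(10, 30), stringsAsFactors = FALSE)
  att_full <- data.frame(record_id = c("N1", "N2"), year = c(2012, 2013),
                         holding_id = c("H1", "H2"),
                         deforestation_related = TRUE,
                         stringsAsFactors = FALSE)
  s_full <- illegality_enforcement_series(labels, att_full)
  expect_equal(s_full$pct_illegal_area_noticed, c(100, 100))
  expect_equal(s_full$pct_holdings_noticed, c(100, 100))
  s_none <- illegality_enforcement_series(labels, att_full[0, ])
  expect_equal(s_none$pct_illegal_area_noticed, c(0, 0))
  expect_equal(s_none$pct_holdings_noticed, c(0, 0))
  ov <- attr(s_full, "overall")
  expect_equal(ov$pct_holdings_noticed, 100)
})

test_that("classification recovers the generator's ground truth exactly", {
  cfg <- small_cfg(seed = 29)
  ls <- generate_landscape(cfg)
  app <- derive_app_zones(ls$streams, ls$rules)
  bal <- compute_fc_balance(ls$holdings, ls$native_map, ls$grid, ls$rules)
  labels <- classify_patches(ls$patches, ls$holdings, bal, app, ls$rules)
  m <- merge(labels, ls$ground_truth, by = "patch_id")
  above <- m[m$true_label != "below_mmu", ]
  expect_equal(mean(above$label == above$true_label), 1)
  expect_equal(mean(above$reason == above$true_reason), 1)
  expect_true(all(m$label[m$true_label == "below_mmu"] == "below_mmu"))
  # the generator's pre-cleared holdings are exactly the non-compliant ones
  expect_equal(bal$compliant, !ls$holdings$lr_deficit_true)
})
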