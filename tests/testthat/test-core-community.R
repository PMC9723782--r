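test_that("temperature classification splits strictly above the threshold", {
  md <- data.frame(sample_id = c("w1", "w2", "w3"),
                   basal_temperature = c(33.2, 5.3, 25.0),
                   substratum = "sulphide", location = "x",
                   sample_type = "tubeworm_grab")
  cls <- classify_temperature(md)
  expect_identical(unname(cls), c("highT", "lowT", "lowT"))
  md$basal_temperature[1] <- NA
  expect_error(classify_temperature(md), "missing basal temperature.*w1")
})

test_that("seed fauna follow the effect threshold by regime", {
  fx <- data.frame(taxon = c("sp1", "sp2", "sp3"),
                   effect = c(1.4, -1.2, 0.3))
  s <- seed_fauna(fx)
  expect_identical(s$highT, "sp1")
  expect_identical(s$lowT, "sp2")
  expect_warning(seed_fauna(data.frame(taxon = "sp1", effect = 0.5)),
                 "no enriched fauna")
})

test_that("enrichment flags fold multiple contrasts into regime evidence", {
  opp <- data.frame(taxon = c("a", "b"), effect = c(1.5, -2))
  dif <- data.frame(taxon = c("a", "c"), effect = c(1.1, 3))
  fl <- enrichment_flags(opp, highT_vs_diffuse = dif)
  a <- fl[fl$taxon == "a" & fl$regime == "highT", ]
  expect_true(a$vs_opposite && a$vs_diffuse)
  expect_true(fl[fl$taxon == "b", "regime"] == "lowT")
  expect_true(fl[fl$taxon == "c", "vs_diffuse"])
})

make_edges <- function(...) {
  e <- data.frame(...)
  e$sign <- ifelse(e$rho > 0, "positive", "negative")
  e
}

test_that("tier rules combine covariance and enrichment as specified", {
  seeds <- list(highT = paste0("f", 1:5), lowT = "g1")
  edges <- make_edges(
    from = c(rep("strongT", 5), rep("modT", 4), "oneT", "negT"),
    to = c(paste0("f", 1:5), paste0("f", 1:4), "f1", "f2"),
    rho = c(0.8, 0.8, 0.8, 0.8, 0.85, 0.8, 0.8, 0.8, 0.8, 0.9, -0.9))
  flags <- data.frame(taxon = c("strongT", "weakT"), regime = "highT",
                      vs_opposite = TRUE, vs_diffuse = c(TRUE, FALSE))
  asg <- tier_taxa(edges, seeds, flags,
                   c("strongT", "modT", "oneT", "weakT", "negT", "nullT"))
  get <- function(t1) asg[asg$taxon == t1, ]
  expect_identical(get("strongT")$tier, "strong")
  expect_identical(get("strongT")$regime, "highT")
  expect_identical(get("strongT")$n_edges_to_fauna, 5L)
  expect_equal(get("strongT")$mean_rho_fauna, 0.81)
  expect_identical(get("modT")$tier, "moderate")
  expect_identical(get("oneT")$tier, "weak")    # single edge, no enrichment
  expect_identical(get("weakT")$tier, "weak")   # enrichment only
  expect_identical(get("negT")$tier, "none")    # negative edges don't count
  expect_identical(get("nullT")$tier, "none")
})

test_that("equal evidence for both regimes is flagged, never dropped", {
  seeds <- list(highT = "f1", lowT = "g1")
  edges <- make_edges(from = c("amb", "amb"), to = c("f1", "g1"),
                      rho = c(0.8, 0.8))
  asg <- tier_taxa(edges, seeds, enrichment_flags(
    data.frame(taxon = character(0), effect = numeric(0))), "amb")
  expect_identical(nrow(asg), 2L)
  expect_true(all(asg$ambiguous))
  expect_setequal(asg$regime, c("highT", "lowT"))
})

test_that("removing all seeds empties the community without crashing", {
  seeds <- list(highT = character(0), lowT = character(0))
  edges <- make_edges(from = "a", to = "b", rho = 0.9)
  asg <- tier_taxa(edges, seeds, enrichment_flags(
    data.frame(taxon = character(0), effect = numeric(0))), c("a", "b"))
  expect_true(all(asg$tier == "none"))
})

test_that("highT sub-clustering recovers planted faunal blocks", {
  fauna <- c("f1", "f2", "f3", "f4")
  r <- matrix(0.1, 6, 6, dimnames = list(c(fauna, "m1", "m2"),
                                         c(fauna, "m1", "m2")))
  r[1:2, 1:2] <- 0.95; r[3:4, 3:4] <- 0.95; diag(r) <- 1
  edges <- make_edges(from = c("m1", "m1", "m2"), to = c("f1", "f3", "f4"),
                      rho = c(0.8, 0.8, 0.8))
  sc <- subcluster_highT(r, fauna, edges)
  expect_identical(unname(sc$fauna["f1"]), unname(sc$fauna["f2"]))
  expect_identical(unname(sc$fauna["f3"]), unname(sc$fauna["f4"]))
  expect_false(sc$fauna[["f1"]] == sc$fauna[["f3"]])
  expect_identical(unname(sc$taxa["m1"]), "HighT 1/2")
  expect_identical(unname(sc$taxa["m2"]), unname(sc$fauna[["f4"]]))
  none <- subcluster_highT(r, "f1", edges)
  expect_identical(unname(none$fauna), "na")
})

test_that("connectivity summarises positive degrees of seed fauna", {
  seeds <- list(highT = c("f1", "f2"), lowT = character(0))
  fauna <- c("f1", "f2", "f3")
  edges <- make_edges(
    from = c("f1", "f1", "f1", "f1", "f2", "f2", "f2", "f2", "f2", "f2"),
    to = c("m1", "m2", "m3", "f3", "m4", "m5", "m6", "m7", "m8", "f3"),
    rho = rep(0.8, 10))
  cs <- connectivity_summary(edges, seeds, fauna)
  h <- cs[cs$regime == "highT", ]
  expect_equal(h$mean_total, 5)          # degrees 4 and 6
  expect_equal(h$sd_total, sqrt(2))
  expect_equal(h$mean_fauna, 1)          # one faunal partner each (f3)
  expect_equal(h$sd_fauna, 0)
  expect_true(is.na(cs[cs$regime == "lowT", "mean_total"]))

  single <- connectivity_summary(edges, list(highT = "f1",
                                             lowT = character(0)), fauna)
  expect_equal(single[1, "sd_total"], 0)  # n = 1: sd reported as 0
})

test_that("network export round-trips edges and writes tier attributes", {
  edges <- make_edges(from = c("B_x", "m_f1"), to = c("m_f1", "M_f2"),
                      rho = c(0.81, -0.9))
  asg <- data.frame(taxon = "B_x", regime = "highT", tier = "strong",
                    n_edges_total = 1, n_edges_to_fauna = 1,
                    mean_rho_fauna = 0.81, vs_opposite = TRUE,
                    vs_diffuse = FALSE, ambiguous = FALSE)
  doms <- c(B_x = "bacteria", m_f1 = "meiofauna", M_f2 = "macrofauna")
  dir <- withr::local_tempdir()
  files <- export_network(edges, asg, doms, file.path(dir, "net"),
                          seeds = list(highT = c("m_f1", "M_f2")))
  back <- read_graphml_edges(files[["graphml"]])
  expect_equal(back[order(back$from), c("from", "to", "rho", "sign")],
               edges[order(edges$from), c("from", "to", "rho", "sign")],
               ignore_attr = TRUE)
  doc <- xml2::read_xml(files[["graphml"]])
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  tiers <- xml2::xml_text(xml2::xml_find_all(
    doc, ".//g:node[@id='B_x']/g:data[@key='tier']", ns))
  expect_identical(tiers, "strong")
  sif <- readLines(files[["sif"]])
  expect_identical(length(sif), 2L)

  empty <- export_network(edges[0, ], asg[0, ], doms,
                          file.path(dir, "empty"))
  expect_identical(nrow(read_graphml_edges(empty[["graphml"]])), 0L)
})
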