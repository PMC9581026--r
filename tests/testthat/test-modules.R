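star_dppis <- function(hub, partners, direction = "activated") {
  data.frame(gene_a = pmin(hub, partners), gene_b = pmax(hub, partners),
             direction = direction, stringsAsFactors = FALSE)
}

test_that("hubs need at least min_edges distinct differential edges", {
  five <- star_dppis("H", paste0("P", 1:5))
  cat5 <- build_modules(five, min_edges = 5)
  expect_named(cat5, "mH")
  expect_equal(length(cat5$mH$members), 5L)
  expect_equal(nrow(cat5$mH$edges), 5L)

  four <- star_dppis("H", paste0("P", 1:4))
  expect_length(build_modules(four, min_edges = 5), 0L)

  # an edge called in both directions counts once towards incidence
  dup_dir <- rbind(star_dppis("H", paste0("P", 1:4), "activated"),
                   star_dppis("H", "P1", "repressed"))
  expect_length(build_modules(dup_dir, min_edges = 5), 0L)
  cat_both <- build_modules(dup_dir, min_edges = 4)
  expect_equal(sort(cat_both$mH$edges$direction),
               c("activated", "activated", "activated", "both"))
})

test_that("overlapping stars yield two modules sharing their bridge edge", {
  dppis <- rbind(star_dppis("H1", c("H2", paste0("A", 1:5))),
                 star_dppis("H2", paste0("B", 1:4)))
  cat <- build_modules(dppis, min_edges = 5)
  expect_setequal(names(cat), c("mH1", "mH2"))
  expect_equal(nrow(cat$mH1$edges), 6L)
  expect_equal(nrow(cat$mH2$edges), 5L)
  bridge <- paste(pmin("H1", "H2"), pmax("H1", "H2"))
  expect_true(bridge %in% paste(cat$mH1$edges$gene_a, cat$mH1$edges$gene_b))
  expect_true(bridge %in% paste(cat$mH2$edges$gene_a, cat$mH2$edges$gene_b))
  # union of module edges stays inside the input dPPI edges
  all_edges <- unique(unlist(lapply(cat, function(m)
    paste(m$edges$gene_a, m$edges$gene_b))))
  expect_true(all(all_edges %in% paste(dppis$gene_a, dppis$gene_b)))
})

test_that("catalog intersection keeps common interactions only", {
  a <- build_modules(star_dppis("H", paste0("P", 1:5)), min_edges = 5)
  b <- build_modules(star_dppis("H", paste0("P", 3:7)), min_edges = 5)
  common <- intersect_catalogs(a, b)
  expect_named(common, "mH")
  expect_setequal(common$mH$members, c("P3", "P4", "P5"))

  # identical catalogs intersect to themselves
  expect_equal(catalog_contents(intersect_catalogs(a, a)),
               catalog_contents(a))
  # disjoint hubs give an empty catalog
  c2 <- build_modules(star_dppis("Z", paste0("P", 1:5)), min_edges = 5)
  expect_length(intersect_catalogs(a, c2), 0L)
})

test_that("direction agreement is required unless relaxed", {
  a <- build_modules(star_dppis("H", paste0("P", 1:5), "activated"),
                     min_edges = 5)
  b <- build_modules(star_dppis("H", paste0("P", 1:5), "repressed"),
                     min_edges = 5)
  expect_length(intersect_catalogs(a, b), 0L)
  relaxed <- intersect_catalogs(a, b, require_direction_agreement = FALSE)
  expect_equal(nrow(relaxed$mH$edges), 5L)
  # "both" matches either single direction, and keeps the agreement
  dup_dir <- rbind(star_dppis("H", paste0("P", 1:5), "activated"),
                   star_dppis("H", paste0("P", 1:5), "repressed"))
  c_both <- build_modules(dup_dir, min_edges = 5)
  mixed <- intersect_catalogs(c_both, a)
  expect_equal(unique(mixed$mH$edges$direction), "activated")
})

test_that("intersection is commutative, idempotent and subset-closed", {
  set.seed(41)
  genes <- c(LETTERS, letters)
  for (i in 1:25) {
    a <- build_modules(random_dppis(genes, sample(10:40, 1)), min_edges = 2)
    b <- build_modules(random_dppis(genes, sample(10:40, 1)), min_edges = 2)
    ab <- intersect_catalogs(a, b)
    ba <- intersect_catalogs(b, a)
    expect_equal(catalog_contents(ab), catalog_contents(ba))
    expect_equal(catalog_contents(intersect_catalogs(a, a)),
                 catalog_contents(a))
    expect_equal(catalog_contents(intersect_catalogs(ab, ab)),
                 catalog_contents(ab))
    for (nm in names(ab)) {
      k_ab <- paste(ab[[nm]]$edges$gene_a, ab[[nm]]$edges$gene_b)
      expect_true(all(k_ab %in% paste(a[[nm]]$edges$gene_a,
                                      a[[nm]]$edges$gene_b)))
      expect_true(all(k_ab %in% paste(b[[nm]]$edges$gene_a,
                                      b[[nm]]$edges$gene_b)))
    }
  }
})

test_that("hub detection matches a naive incidence count", {
  set.seed(53)
  genes <- sprintf("g%02d", 1:20)
  for (i in 1:10) {
    dppis <- random_dppis(genes, sample(10:50, 1))
    min_e <- sample(2:4, 1)
    cat <- build_modules(dppis, min_edges = min_e)
    edges <- unique(dppis[, c("gene_a", "gene_b")])
    naive_hubs <- sort(Filter(function(g)
      sum(edges$gene_a == g | edges$gene_b == g) >= min_e, genes))
    expect_equal(sort(vapply(cat, `[[`, "", "hub")), naive_hubs,
                 ignore_attr = TRUE)
  }
})

test_that("module summary reports sizes and hub sharing", {
  solo <- build_modules(star_dppis("H", paste0("P", 1:5)), min_edges = 5)
  s1 <- module_summary(solo)
  expect_equal(s1$hub_sharing_degree, 0L)
  expect_equal(s1$n_edges, 5L)

  # hub A is a member of modules mB and mC
  dppis <- rbind(star_dppis("A", paste0("x", 1:4)),
                 star_dppis("B", c("A", paste0("y", 1:3))),
                 star_dppis("C", c("A", paste0("z", 1:3))))
  cat <- build_modules(dppis, min_edges = 4)
  s2 <- module_summary(cat)
  expect_equal(s2$hub_sharing_degree[s2$hub == "A"], 2L)

  s0 <- module_summary(build_modules(
    data.frame(gene_a = character(), gene_b = character(),
               direction = character())))
  expect_equal(nrow(s0), 0L)
})
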