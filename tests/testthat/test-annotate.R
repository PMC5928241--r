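test_that("CGI categories honor boundaries, strand and precedence", {
  ann <- toy_annotation()
  # island A [10000, 11000), + strand gene gA (tss 10100, tes 15000)
  expect_equal(assign_cgi_category(probes_at(10501), ann), "Island")
  expect_equal(assign_cgi_category(probes_at(10001), ann), "Island")
  expect_equal(assign_cgi_category(probes_at(11000), ann), "Island")
  # 500 bp upstream of the left edge -> Shore5; 2500 bp -> beyond shores
  expect_equal(assign_cgi_category(probes_at(10000 - 500 + 1), ann),
               "Shore5")
  expect_equal(assign_cgi_category(probes_at(10000 - 2500 + 1), ann),
               "Other")
  expect_equal(assign_cgi_category(probes_at(10000 - 2000 + 1), ann),
               "Shore5") # exactly 2 kb: still shore
  # right of island A: Shore3 for 2 kb, then gene body up to the TES
  expect_equal(assign_cgi_category(probes_at(11000 + 1500), ann), "Shore3")
  expect_equal(assign_cgi_category(probes_at(13500), ann), "GeneBody")
  expect_equal(assign_cgi_category(probes_at(15200), ann), "Other")
  # island B has a - strand gene: left flank is its 3' shore and the gene
  # body runs leftwards from start - 2 kb to the TES at 26000
  expect_equal(assign_cgi_category(probes_at(30000 - 500 + 1), ann),
               "Shore3")
  expect_equal(assign_cgi_category(probes_at(30800 + 500), ann), "Shore5")
  expect_equal(assign_cgi_category(probes_at(27500), ann), "GeneBody")
  # island C has no gene within 10 kb: genomic orientation, left = 5'
  expect_equal(assign_cgi_category(probes_at(50000 - 100 + 1), ann),
               "Shore5")
  expect_equal(assign_cgi_category(probes_at(50400 + 100), ann), "Shore3")
})

test_that("every probe gets exactly one category and oracle layouts agree", {
  cfg <- small_config(n_probes = 300, seed = 61)
  gen <- generate_probe_annotation(cfg)
  got <- assign_cgi_category(gen$probes, gen$annotation)
  expect_true(all(got %in% c("Island", "Shore5", "Shore3", "GeneBody",
                             "Other")))
  want <- vapply(gen$probes$pos, cgi_oracle, character(1),
                 ann = gen$annotation)
  expect_identical(got, want)
})

test_that("signed TSS distance reflects transcription direction", {
  genes <- toy_annotation()$genes
  # probe exactly at gA's TSS
  expect_equal(signed_tss_distance(probes_at(10101), genes), 0)
  # + strand: probe 1 kb right of the TSS is downstream (+1000)
  expect_equal(signed_tss_distance(probes_at(11101), genes), 1000)
  # - strand gene gB (tss 30700): 1 kb right is upstream (-1000)
  expect_equal(signed_tss_distance(probes_at(31701), genes), -1000)
  expect_equal(nearest_gene(probes_at(c(10101, 31701)), genes),
               c("gA", "gB"))
  # equidistant TSSs: tie goes to the smaller gene id
  tie_genes <- data.frame(chrom = "chr1", tss = c(1000L, 3000L),
                          tes = c(2500L, 4500L), strand = c("+", "+"),
                          gene_id = c("gB2", "gA1"),
                          stringsAsFactors = FALSE)
  expect_equal(nearest_gene(probes_at(2001), tie_genes), "gA1")
})

test_that("TSS distances match an all-pairs scan on random layouts", {
  set.seed(62)
  genes <- data.frame(chrom = "chr1",
                      tss = sample.int(100000, 30),
                      tes = 0L, strand = sample(c("+", "-"), 30, TRUE),
                      gene_id = sprintf("g%02d", 1:30),
                      stringsAsFactors = FALSE)
  genes$tes <- genes$tss + ifelse(genes$strand == "+", 500L, -500L)
  pr <- probes_at(sample.int(100000, 200))
  got <- signed_tss_distance(pr, genes)
  want <- vapply(pr$pos - 1L, function(p0) {
    ad <- abs(p0 - genes$tss)
    cand <- which(ad == min(ad))
    j <- cand[order(genes$gene_id[cand])][1]
    if (genes$strand[j] == "+") p0 - genes$tss[j] else genes$tss[j] - p0
  }, numeric(1))
  expect_equal(got, want)
})

test_that("island-scaled coordinates map edges, midpoints and flanks", {
  ann <- toy_annotation()
  # island A (+ orientation), width 1000
  expect_equal(scaled_island_coordinate(probes_at(10001), ann), 0)
  expect_equal(scaled_island_coordinate(probes_at(11001), ann), 1)
  expect_equal(scaled_island_coordinate(probes_at(10501), ann), 0.5)
  # 1250 bp into the 5' flank maps to -1250
  expect_equal(scaled_island_coordinate(probes_at(10000 - 1250 + 1), ann),
               -1250)
  # 100 bp past the 3' edge maps to 1 + 100
  expect_equal(scaled_island_coordinate(probes_at(11000 + 100 + 1), ann),
               101)
  # outside the +/- 2.5 kb window: NA
  expect_true(is.na(scaled_island_coordinate(probes_at(14000), ann)))
  # island B is - oriented: its 5' edge is the right edge
  expect_equal(scaled_island_coordinate(probes_at(30801), ann), 0)
  expect_equal(scaled_island_coordinate(probes_at(30000 + 1), ann), 1)
  expect_error(scaled_island_coordinate(
    probes_at(100),
    genome_annotation(data.frame(chrom = "chr1", start = 1L, end = 1L),
                      toy_annotation()$genes,
                      toy_annotation()$chromatin)),
    "half-open")
})

test_that("chromatin states are looked up and merged correctly", {
  ann <- toy_annotation()
  # segment [9000, 10000) has state 10 -> merged into Transcribed Regions
  expect_equal(assign_chromatin_state(probes_at(9500), ann),
               "Transcribed Regions")
  # state 1 is not merged
  expect_equal(assign_chromatin_state(probes_at(500), ann), "1")
  expect_equal(assign_chromatin_state(probes_at(3500), ann),
               "Strong Enhancer")
  expect_equal(assign_chromatin_state(probes_at(6500), ann),
               "Weak Enhancer")
  # probe beyond the tiling: Unassigned with a warning
  expect_warning(got <- assign_chromatin_state(probes_at(70000), ann),
                 "Unassigned")
  expect_equal(got, "Unassigned")
  # full tiling matches a linear-scan oracle
  cfg <- small_config(n_probes = 300, seed = 63)
  gen <- generate_probe_annotation(cfg)
  got <- assign_chromatin_state(gen$probes, gen$annotation)
  seg <- gen$annotation$chromatin
  want <- vapply(gen$probes$pos - 1L, function(p0) {
    seg$state[seg$start <= p0 & p0 < seg$end][1]
  }, character(1))
  mm <- default_state_merge()
  want <- unname(ifelse(is.na(mm[want]), want, mm[want]))
  expect_identical(got, want)
})

test_that("set overlaps follow exact set algebra", {
  expect_equal(set_overlap(c("g1", "g2"), c("g2", "g3")),
               c(both = 1L, a_only = 1L, b_only = 1L))
  expect_equal(set_overlap(c("a", "b"), c("a", "b")),
               c(both = 2L, a_only = 0L, b_only = 0L))
  set.seed(64)
  for (i in 1:20) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    got <- set_overlap(a, b)
    expect_equal(unname(got["both"]), length(intersect(a, b)))
    expect_equal(sum(got), length(union(a, b)))
  }
})
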