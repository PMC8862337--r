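toy_genes <- function(n_per_chr, chrs = c("c1", "c2")) {
  do.call(rbind, lapply(chrs, function(ch) {
    data.frame(gene_id = sprintf("%s_g%02d", ch, seq_len(n_per_chr)),
               chromosome = ch,
               start = (seq_len(n_per_chr) - 1) * 2000 + 1,
               end = (seq_len(n_per_chr) - 1) * 2000 + 1000,
               strand = "+", stringsAsFactors = FALSE)
  }))
}

test_that("ranks are dense per chromosome with deterministic tie-breaks", {
  g <- toy_genes(3)
  rk <- assign_ranks(g)
  expect_equal(rk$rank[rk$chromosome == "c1"], 0:2)
  expect_equal(rk$rank[rk$chromosome == "c2"], 0:2)

  ov <- data.frame(gene_id = c("a", "b"), chromosome = "c1",
                   start = c(100, 100), end = c(500, 300), strand = "+")
  rk2 <- assign_ranks(ov)
  expect_equal(rk2$gene_id[rk2$rank == 0], "b") # shorter end first

  expect_error(assign_ranks(data.frame(gene_id = c("a", "a"),
                                       chromosome = "c1", start = 1:2,
                                       end = 3:4, strand = "+")),
               class = "gsl_validation_error")
})

test_that("GFF3 gene features round-trip through the reader", {
  gff <- c("##gff-version 3",
           "c1\ttest\tgene\t101\t1100\t.\t+\t.\tID=geneA",
           "c1\ttest\tmRNA\t101\t1100\t.\t+\t.\tID=t1;Parent=geneA",
           "c1\ttest\tgene\t2101\t3100\t.\t-\t.\tID=geneB")
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  g <- read_gene_models(f)
  expect_equal(g$gene_id, c("geneA", "geneB"))
  expect_equal(g$start, c(101, 2101))
  expect_equal(g$strand, c("+", "-"))
})

test_that("chaining finds planted blocks and respects the threshold", {
  g <- toy_genes(10)
  # 6 collinear anchors c1_g01..g06 <-> c2_g01..g06
  pairs <- data.frame(gene_a = sprintf("c1_g%02d", 1:6),
                      gene_b = sprintf("c2_g%02d", 1:6))
  rk <- assign_ranks(g)
  blocks <- find_collinear_blocks(pairs, rk)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 6)

  few <- find_collinear_blocks(pairs[1:4, ], rk, min_anchors = 5)
  expect_length(few, 0)

  # inverted block: second chromosome runs backwards
  inv <- data.frame(gene_a = sprintf("c1_g%02d", 1:5),
                    gene_b = sprintf("c2_g%02d", 5:1))
  binv <- find_collinear_blocks(inv, rk)
  expect_length(binv, 1)
  expect_equal(binv[[1]]$orientation, -1L)
})

test_that("chaining matches the exhaustive subset oracle on small instances", {
  set.seed(13)
  for (rep in 1:12) {
    n_anchor <- sample(4:10, 1)
    g <- toy_genes(30)
    ra <- sort(sample(0:29, n_anchor))
    rb <- sample(0:29, n_anchor)
    pairs <- data.frame(gene_a = sprintf("c1_g%02d", ra + 1),
                        gene_b = sprintf("c2_g%02d", rb + 1))
    rk <- assign_ranks(g)
    max_gap <- sample(c(5, 10, 25), 1)
    blocks <- find_collinear_blocks(pairs, rk, min_anchors = 2,
                                    max_rank_gap = max_gap)
    got <- if (length(blocks) == 0) 1 else max(vapply(blocks, function(b) {
      nrow(b$anchors)
    }, 0))
    ref <- oracle_best_chain_size(ra, rb, max_gap)
    expect_equal(got, max(ref, 1), info = sprintf("rep %d", rep))
  }
})

test_that("category calls follow the documented priority", {
  g <- toy_genes(12)
  rk <- assign_ranks(g)
  # adjacent homologs -> tandem
  pairs <- data.frame(gene_a = "c1_g05", gene_b = "c1_g06")
  calls <- classify_duplicates(rk, pairs)
  got <- setNames(calls$category, calls$gene_id)
  expect_equal(got[["c1_g05"]], "tandem")
  expect_equal(got[["c1_g06"]], "tandem")
  expect_equal(got[["c1_g01"]], "singleton")

  # same chromosome, rank distance 3 -> proximal; distance 11 -> dispersed
  pairs2 <- data.frame(gene_a = c("c1_g01", "c2_g01"),
                       gene_b = c("c1_g04", "c2_g12"))
  calls2 <- classify_duplicates(rk, pairs2)
  got2 <- setNames(calls2$category, calls2$gene_id)
  expect_equal(got2[["c1_g01"]], "proximal")
  expect_equal(got2[["c1_g04"]], "proximal")
  expect_equal(got2[["c2_g01"]], "dispersed")

  # different chromosomes, no block -> dispersed
  pairs3 <- data.frame(gene_a = "c1_g01", gene_b = "c2_g07")
  got3 <- setNames(classify_duplicates(rk, pairs3)$category,
                   classify_duplicates(rk, pairs3)$gene_id)
  expect_equal(got3[["c1_g01"]], "dispersed")

  expect_error(classify_duplicates(rk, data.frame(gene_a = "nope",
                                                  gene_b = "c1_g01")),
               class = "gsl_validation_error")
})

test_that("every gene gets exactly one category and counts partition", {
  gn <- gen_genome(c(tandem = 10, proximal = 6, segmental = 20,
                     dispersed = 12, singleton = 12), seed = 3)
  rk <- assign_ranks(gn$genes)
  calls <- classify_duplicates(rk, gn$pairs)
  expect_equal(nrow(calls), nrow(gn$genes))
  expect_equal(sum(duplication_summary(calls)$n), nrow(gn$genes))
  truth <- setNames(gn$truth$category, gn$truth$gene_id)
  expect_equal(unname(truth[calls$gene_id]), calls$category)
})

test_that("widening the proximal window never shrinks tandem+proximal", {
  gn <- gen_genome(c(tandem = 6, proximal = 6, segmental = 0,
                     dispersed = 8, singleton = 8), seed = 5)
  rk <- assign_ranks(gn$genes)
  count_near <- function(gap) {
    calls <- classify_duplicates(rk, gn$pairs, proximal_max_gap = gap)
    sum(calls$category %in% c("tandem", "proximal"))
  }
  gaps <- c(2, 5, 10, 20)
  counts <- vapply(gaps, count_near, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("tandem pair and gene counts follow array structure", {
  g <- toy_genes(10)
  rk <- assign_ranks(g)
  one <- tandem_pair_count(data.frame(gene_a = "c1_g03", gene_b = "c1_g04"), rk)
  expect_equal(one, list(n_pairs = 1L, n_genes = 2L))
  # array of three consecutive homologs: 2 pairs, 3 genes
  arr <- data.frame(gene_a = c("c1_g03", "c1_g04"),
                    gene_b = c("c1_g04", "c1_g05"))
  expect_equal(tandem_pair_count(arr, rk), list(n_pairs = 2L, n_genes = 3L))
  none <- tandem_pair_count(data.frame(gene_a = character(0),
                                       gene_b = character(0)), rk)
  expect_equal(none, list(n_pairs = 0L, n_genes = 0L))
})
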