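test_that("GFF3 gene models parse with strand-aware TSS and derived introns", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=GENEA;Name=GENEA",
    "chr1\ttest\texon\t1000\t1200\t.\t+\t.\tID=GENEA.e1;Parent=GENEA",
    "chr1\ttest\texon\t1800\t2000\t.\t+\t.\tID=GENEA.e2;Parent=GENEA",
    "chr1\ttest\tgene\t5000\t6000\t.\t-\t.\tID=LOC123;Name=LOC123"), path)
  models <- read_gff3(path)
  g <- models$genes[order(models$genes$gene_id), ]
  expect_equal(g$tss, c(1000, 6000))       # TSS at the 5' end per strand
  expect_equal(g$characterized, c(TRUE, FALSE))
  # the gap between GENEA's exons is intronic; the second exon is past the
  # promoter window (which covers the first 200 bp of the body)
  expect_equal(assign_region("chr1", 1500, models)$region, "intron")
  expect_equal(assign_region("chr1", 1900, models)$region, "exon")
  # a gene without exon records acts as single-exon
  expect_equal(assign_region("chr1", 5500, models)$region, "exon")
})

test_that("region windows and priority order follow the annotation rules", {
  g <- gene_models(
    data.frame(gene_id = c("GENEA", "GENEB"), chrom = "chr1",
               strand = c("+", "-"), start = c(10000, 40000),
               end = c(12000, 44000), characterized = TRUE),
    data.frame(gene_id = c("GENEA", "GENEB"), start = c(10000, 40000),
               end = c(12000, 44000)))
  # + strand gene, TSS at 10000
  expect_equal(assign_region("chr1", 9900, g)$region, "TSS")      # 100 bp 5'
  expect_equal(assign_region("chr1", 10050, g)$region, "TSS")     # 50 bp 3'
  expect_equal(assign_region("chr1", 9500, g)$region, "promoter") # 500 bp 5'
  expect_equal(assign_region("chr1", 10500, g)$region, "exon")    # body past the promoter tail
  expect_equal(assign_region("chr1", 7000, g)$region, "upstream") # beyond the 2-kb promoter
  expect_equal(assign_region("chr1", 13000, g)$region, "downstream")
  # - strand gene, TSS at 44000: mirrored windows
  expect_equal(assign_region("chr1", 44100, g)$region, "TSS")
  expect_equal(assign_region("chr1", 44500, g)$region, "promoter")
  expect_equal(assign_region("chr1", 47000, g)$region, "upstream")
  expect_equal(assign_region("chr1", 39000, g)$region, "downstream")
  # nothing within 10 kb
  expect_equal(assign_region("chr1", 60000, g)$region, "intergenic")
  expect_true(is.na(assign_region("chr1", 60000, g)$gene_id))
  expect_equal(assign_region("chr2", 10000, g)$region, "intergenic")
})

test_that("a promoter of one gene outranks flanks and bodies resolve by priority", {
  # site in GENEC's promoter AND 10-kb downstream of GENEA: promoter wins
  g <- gene_models(
    data.frame(gene_id = c("GENEA", "GENEC"), chrom = "chr1",
               strand = "+", start = c(1000, 9500), end = c(2000, 12000),
               characterized = TRUE),
    data.frame(gene_id = c("GENEA", "GENEC"), start = c(1000, 9500),
               end = c(2000, 12000)))
  a <- assign_region("chr1", 8000, g)
  expect_equal(a$region, "promoter")
  expect_equal(a$gene_id, "GENEC")
  # a site in one gene's exon and another's promoter: promoter wins
  g2 <- gene_models(
    data.frame(gene_id = c("GENED", "GENEE"), chrom = "chr1",
               strand = "+", start = c(1000, 3500), end = c(3000, 6000),
               characterized = TRUE),
    data.frame(gene_id = c("GENED", "GENEE"), start = c(1000, 3500),
               end = c(3000, 6000)))
  a2 <- assign_region("chr1", 2500, g2)  # exon of GENED, promoter of GENEE
  expect_equal(a2$region, "promoter")
  expect_equal(a2$gene_id, "GENEE")
  # TSS-region sites never report promoter even though windows nest
  a3 <- assign_region("chr1", 3400, g2)  # 100 bp 5' of GENEE's TSS
  expect_equal(a3$region, "TSS")
})

test_that("up/downstream conflicts use the characterized-then-distance tie-break", {
  g <- gene_models(
    data.frame(gene_id = c("GENEA", "LOC1B"), chrom = "chr1",
               strand = "+", start = c(1000, 15000), end = c(2000, 16000),
               characterized = c(TRUE, FALSE)),
    data.frame(gene_id = c("GENEA", "LOC1B"), start = c(1000, 15000),
               end = c(2000, 16000)))
  # 5 kb downstream of characterized GENEA, 8 kb upstream of LOC1B:
  # the characterized gene wins despite upstream's higher class rank
  a <- assign_region("chr1", 7000, g)
  expect_equal(a$gene_id, "GENEA")
  expect_equal(a$region, "downstream")
  expect_equal(a$distance, 5000)
  # both characterized: nearest gene body wins
  g2 <- g; g2$genes$characterized <- TRUE
  g2$genes$gene_id <- c("GENEA", "GENEB")
  g2$exons$gene_id <- c("GENEA", "GENEB")
  a2 <- assign_region("chr1", 11000, g2)  # 9 kb down of A, 4 kb up of B
  expect_equal(a2$gene_id, "GENEB")
  expect_equal(a2$region, "upstream")
  # equal distance: lexicographic id
  a3 <- assign_region("chr1", 8500, g2)   # 6.5 kb from both bodies
  expect_equal(a3$gene_id, "GENEA")
})

test_that("vectorized annotation equals the all-pairs oracle and ignores gene order", {
  cfg <- sim_config(seed = 331, n_cpgs = 300, n_genes = 50)
  models <- simulate_annotation(cfg)
  expect_gte(nrow(models$genes), 40)
  d <- simulate_design(cfg)
  sim <- simulate_methylation(cfg, d)
  sites <- sim$matrix$sites
  ann <- annotate_all(sites, models)$assignments
  for (i in seq_len(nrow(sites))) {
    o <- annotate_oracle(sites$chrom[i], sites$pos[i], models)
    expect_equal(ann$region[i], o$region,
                 info = paste(sites$chrom[i], sites$pos[i]))
    expect_equal(ann$gene_id[i], o$gene_id,
                 info = paste(sites$chrom[i], sites$pos[i]))
  }
  # determinism under input permutation
  perm <- models
  set.seed(333)
  ord <- sample(nrow(perm$genes))
  perm$genes <- perm$genes[ord, ]
  ann2 <- annotate_all(sites, perm)$assignments
  expect_equal(ann2, ann)
  # flank distances never exceed 10 kb
  fl <- ann[ann$region %in% c("upstream", "downstream"), ]
  expect_true(all(fl$distance >= 1 & fl$distance <= 10000))
  expect_true(all(ann$distance[ann$region %in% c("exon", "intron")] == 0))
})

test_that("an empty gene set leaves every site intergenic", {
  g <- gene_models(
    data.frame(gene_id = "GENEZ", chrom = "chrZ", strand = "+",
               start = 1000, end = 2000, characterized = TRUE),
    data.frame(gene_id = "GENEZ", start = 1000, end = 2000))
  sites <- data.frame(chrom = "chr1", pos = c(500L, 1500L, 9000L))
  out <- annotate_all(sites, g)
  expect_true(all(out$assignments$region == "intergenic"))
  expect_equal(unname(out$counts[["intergenic"]]), 3)
})
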