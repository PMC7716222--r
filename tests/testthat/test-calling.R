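params <- call_params()

test_that("read trimming follows the 5'/3' contract and length floor", {
  # single-end length 60: 60 - 20 = 40, kept at the boundary
  r60 <- make_read(1000, ref_seq(1000, 60))
  t60 <- trim_reads(r60, params)
  expect_equal(nchar(t60$seq), 40L)
  expect_equal(t60$start, 1020L)
  expect_identical(t60$seq, ref_seq(1020, 40))

  # single-end length 59 falls under the 40 bp floor and is discarded
  expect_equal(nrow(trim_reads(make_read(1000, ref_seq(1000, 59)), params)),
               0L)

  # paired read of length 150 loses 20 from each end
  r150 <- make_read(2000, ref_seq(2000, 150), paired = TRUE)
  t150 <- trim_reads(r150, params)
  expect_equal(nchar(t150$seq), 110L)
  expect_equal(t150$start, 2020L)

  # reverse-strand 5' end is the right-hand end of the alignment
  rrev <- make_read(3000, ref_seq(3000, 60), strand = "-")
  trev <- trim_reads(rrev, params)
  expect_equal(trev$start, 3000L)
  expect_identical(trev$seq, ref_seq(3000, 40))

  # trimming across an insertion-bearing CIGAR keeps the alignment valid
  rins <- make_read(4000, paste0(ref_seq(4000, 30), "A", ref_seq(4030, 40)),
                    cigar = "30M1I40M")
  tins <- trim_reads(rins, params)
  expect_equal(tins$cigar, "10M1I40M")
  expect_equal(tins$start, 4020L)
})

test_that("the neighborhood quality filter masks around low-quality bases", {
  seq50 <- ref_seq(5000, 50)
  q40 <- strrep("I", 50)

  clean <- quality_mask(make_read(5000, seq50, qual = q40), params)
  expect_false(grepl("N", clean$seq))

  # one Q10 base masks itself and its 5 neighbors on each side
  qbad <- q40
  substr(qbad, 20, 20) <- "+"  # Phred 10
  masked <- quality_mask(make_read(5000, seq50, qual = qbad), params)
  chars <- strsplit(masked$seq, "")[[1]]
  expect_true(all(chars[15:25] == "N"))
  expect_true(all(chars[c(1:14, 26:50)] != "N"))

  # quality exactly 30 everywhere passes: the thresholds are minima
  q30 <- strrep("?", 50)  # Phred 30
  expect_false(grepl("N", quality_mask(make_read(5000, seq50, qual = q30),
                                       params)$seq))

  # masking cannot leak between adjacent reads
  two <- bind_reads(make_read(5000, seq50, qual = qbad, id = "a"),
                    make_read(5000, seq50, qual = q40, id = "b"))
  m2 <- quality_mask(two, params)
  expect_false(grepl("N", m2$seq[2]))
})

test_that("pileup columns count by strand and wrap the circular origin", {
  reads <- bind_reads(
    make_read(100, ref_seq(100, 51), id = "a"),
    make_read(100, ref_seq(100, 51), strand = "-", id = "b")
  )
  pl <- build_pileup(reads, test_ref)
  expect_equal(unname(rowSums(pl$counts[100:150, ])), rep(2, 51))
  expect_true(all(pl$counts[100:150, 1:5] <= 1))  # one per strand
  expect_equal(sum(pl$counts[-(100:150), ]), 0)

  # read spanning the origin: 16560..16569 then 1..10
  wrap <- make_read(16560, paste0(ref_seq(16560, 10),
                                  substr(test_ref$sequence, 1, 10)))
  plw <- build_pileup(wrap, test_ref)
  expect_equal(sum(rowSums(plw$counts[16560:16569, ])), 10)
  expect_equal(sum(rowSums(plw$counts[1:10, ])), 10)

  # empty stack gives an empty pileup
  ple <- build_pileup(trim_reads(make_read(1, ref_seq(1, 10))), test_ref)
  expect_equal(sum(ple$counts), 0)

  # masked bases contribute nothing
  qbad <- strrep("!", 51)
  plm <- build_pileup(quality_mask(make_read(100, ref_seq(100, 51),
                                             qual = qbad), params), test_ref)
  expect_equal(sum(plm$counts), 0)

  # deletions and insertions are registered from the CIGAR
  rid <- make_read(7000, paste0(ref_seq(7000, 20), "T", ref_seq(7025, 20)),
                   cigar = "20M1I5D20M")
  pli <- build_pileup(rid, test_ref)
  expect_equal(unname(rowSums(pli$counts[7020:7024, c(5, 10)])), rep(1, 5))
  expect_equal(pli$insertions$position, 7019L)
  expect_equal(pli$insertions$motif, "T")
})

test_that("column calling applies depth, frequency and strand rules", {
  # 950 C / 50 T balanced on both strands, ref C: a 5% PHP with the
  # appropriate pyrimidine code and recorded major frequency
  cl <- call_column(c(0, 475, 0, 25, 0, 0, 475, 0, 25, 0), "C", params)
  expect_equal(cl$status, "php")
  expect_equal(cl$call, "Y")
  expect_equal(cl$major_base, "C")
  expect_equal(cl$major_freq, 0.95)

  # depth 99 never yields a call
  expect_equal(call_column(c(0, 49, 0, 0, 0, 0, 50, 0, 0, 0), "C",
                           params)$status, "no_call_depth")

  # 4.9% sits below the 5% threshold: reference call
  expect_equal(call_column(c(0, 476, 0, 24, 0, 0, 475, 0, 25, 0), "C",
                           params)$status, "reference")

  # 50 A reads all on one strand fail the 1% opposite-strand support and
  # the balanced G majority is reported as a fixed substitution over ref A
  cl2 <- call_column(c(50, 0, 500, 0, 0, 0, 0, 450, 0, 0), "A", params)
  expect_equal(cl2$status, "substitution")
  expect_equal(cl2$call, "G")

  # more than two retained alleles is a mixture-suspect site, not a call
  expect_equal(call_column(c(400, 150, 150, 100, 0, 400, 150, 150, 100, 0),
                           "A", params)$status, "mixture_suspect")

  # equal counts for two non-reference bases: both retained as a PHP with
  # the alphabetically first base designated major
  tie <- call_column(c(0, 250, 250, 0, 0, 0, 250, 250, 0, 0), "T", params)
  expect_equal(tie$status, "php")
  expect_equal(tie$call, "S")
  expect_equal(tie$major_base, "C")

  # a deletion allele competes as a base class
  del <- call_column(c(0, 0, 0, 0, 500, 0, 0, 0, 0, 500), "C",
                     params)
  expect_equal(del$status, "deletion")
})

test_that("noiseless simulations are recovered exactly by call_profile", {
  toks <- c(transition_token(2100), transition_token(2500))
  prof <- profile_from_strings("S1", toks, test_ref)
  cfg <- sim_config(depth_mean = 500, base_error_rate = 0,
                    php_individual_rate = 0)
  pl <- simulate_pileup(prof, test_ref, cfg, range = c(2000, 2600), seed = 4)
  res <- call_profile(pl, test_ref, params, range = c(2000, 2600), "S1")
  expect_setequal(format_variant(res$profile$variants), toks)
  expect_length(res$metrics$positions_below_min_depth, 0)
  expect_equal(res$metrics$average_major_base_frequency, 1)
})

test_that("a 10% heteroplasmy at np 16093 is detected at 1000x", {
  rb <- substr(test_ref$sequence, 16093, 16093)
  alt <- c(A = "G", G = "A", C = "T", T = "C")[[rb]]
  v <- new_variant(16093, "substitution", ref = rb,
                   call = mitohap:::iupac_code_for(rb, alt),
                   major_freq = 0.9, major_base = rb)
  prof <- mito_profile("S", v)
  cfg <- sim_config(depth_mean = 1000, base_error_rate = 0.005)
  pl <- simulate_pileup(prof, test_ref, cfg, range = c(16000, 16150),
                        seed = 9)
  res <- call_profile(pl, test_ref, params, range = c(16000, 16150))
  hit <- res$profile$variants[res$profile$variants$position == 16093, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$is_php)
  expect_equal(hit$call, v$call)
  expect_lt(abs(hit$major_freq - 0.9), 0.03)
})

test_that("coverage gaps are excluded from the range and listed", {
  prof <- mito_profile("S")
  cfg <- sim_config(depth_mean = 400, base_error_rate = 0)
  pl <- simulate_pileup(prof, test_ref, cfg,
                        range = rbind(c(7900, 7999), c(8101, 8200)), seed = 2)
  res <- call_profile(pl, test_ref, params, range = c(7900, 8200))
  expect_true(all(8000:8100 %in% res$metrics$positions_below_min_depth))
  expect_false(any(mitohap:::in_intervals(8000:8100, res$profile$range)))
  expect_error(call_profile(pl, test_ref, params, range = c(9000, 9100)),
               "no covered positions")
})

test_that("indels in length-heteroplasmy regions are withheld for the
           read-count analysis", {
  v <- new_variant(309, "insertion", call = "C", insert_index = 1L)
  prof <- mito_profile("S", v)
  cfg <- sim_config(depth_mean = 500, base_error_rate = 0)
  pl <- simulate_pileup(prof, test_ref, cfg, range = c(250, 400), seed = 3)
  res <- call_profile(pl, test_ref, params, range = c(250, 400))
  expect_false("309.1C" %in% format_variant(res$profile$variants))
  wh <- attr(res$profile, "withheld_indels")
  expect_true("309.1C" %in% format_variant(wh))
})

test_that("the NUMT screen partitions alleles around the two thresholds", {
  prof <- mito_profile("S")
  # spike at 3%: visible to the screen, invisible to the 5% profile
  cfg3 <- sim_config(depth_mean = 1500, base_error_rate = 0.003,
                     numt = list(fraction = 0.03, n_diff_sites = 4))
  pl3 <- simulate_pileup(prof, test_ref, cfg3, range = c(6636, 7200),
                         seed = 21)
  truth <- attr(pl3, "numt_truth")
  scr <- numt_screen(pl3, test_ref, params, range = c(6636, 7200))
  expect_true(all(truth$position %in% scr$position))
  expect_true(all(scr$in_numt_region[scr$position %in% truth$position]))
  res3 <- call_profile(pl3, test_ref, params, range = c(6636, 7200))
  expect_false(any(truth$position %in% res3$profile$variants$position))

  # clean data screens clean
  cfg0 <- sim_config(depth_mean = 1500, base_error_rate = 0.003)
  pl0 <- simulate_pileup(prof, test_ref, cfg0, range = c(6636, 7200),
                         seed = 22)
  expect_equal(nrow(numt_screen(pl0, test_ref, params,
                                range = c(6636, 7200))), 0L)

  # a 6% spike crosses into the profile as a PHP and leaves the screen
  cfg6 <- sim_config(depth_mean = 1500, base_error_rate = 0.003,
                     numt = list(fraction = 0.06, n_diff_sites = 3))
  pl6 <- simulate_pileup(prof, test_ref, cfg6, range = c(6636, 7200),
                         seed = 23)
  t6 <- attr(pl6, "numt_truth")
  res6 <- call_profile(pl6, test_ref, params, range = c(6636, 7200))
  called <- res6$profile$variants
  expect_true(all(t6$position %in% called$position[called$is_php]))
  scr6 <- numt_screen(pl6, test_ref, params, range = c(6636, 7200))
  expect_false(any(t6$position %in% scr6$position))
})

test_that("SAM import applies the admission contract and round-trips reads", {
  reads <- bind_reads(
    make_read(1000, ref_seq(1000, 60), id = "keep1"),
    make_read(2000, ref_seq(2000, 60), strand = "-", paired = TRUE,
              id = "keep2"),
    make_read(7000, paste0(ref_seq(7000, 20), "T", ref_seq(7025, 20)),
              cigar = "20M1I5D20M", id = "keep3")
  )
  path <- tempfile(fileext = ".sam")
  write_sam(reads, path, test_ref)
  # append a clipped read, which the length-fraction contract rejects
  cat(paste("clip", 0, test_ref$name, 3000, 60, "10S50M", "*", 0, 0,
            ref_seq(3000, 60), strrep("I", 60), sep = "\t"), "\n",
      file = path, append = TRUE, sep = "")
  back <- read_sam(path)
  expect_setequal(back$read_id, c("keep1", "keep2", "keep3"))
  got <- back[match(reads$read_id, back$read_id), ]
  expect_equal(got$start, reads$start)
  expect_equal(got$cigar, reads$cigar)
  expect_equal(got$strand, reads$strand)
  expect_equal(got$paired, reads$paired)
  expect_equal(got$seq, reads$seq)
})

test_that("the pileup TSV dialect round-trips counts and insertions", {
  reads <- bind_reads(
    make_read(100, ref_seq(100, 51), id = "a"),
    make_read(100, ref_seq(100, 51), strand = "-", id = "b"),
    make_read(7000, paste0(ref_seq(7000, 20), "T", ref_seq(7025, 20)),
              cigar = "20M1I5D20M", id = "c")
  )
  pl <- build_pileup(reads, test_ref)
  path <- tempfile(fileext = ".tsv")
  write_pileup_tsv(pl, path, test_ref)
  back <- read_pileup_tsv(path, test_ref)
  expect_equal(back$counts, pl$counts)
  expect_equal(back$insertions$position, pl$insertions$position)
  expect_equal(back$insertions$motif, pl$insertions$motif)
})
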