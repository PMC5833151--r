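mk_aln <- function(...) {
  args <- list(...)
  as_alignment(seq_set(lapply(names(args), function(id) {
    seq_record(id, args[[id]])
  })))
}

test_that("alignment summaries: length, nseq, avg_pid", {
  a <- mk_aln(s1 = "ACGT", s2 = "ACGA")
  expect_equal(aln_summary(a, "length"), 4L)
  expect_equal(aln_summary(a, "nseq"), 2L)
  expect_equal(aln_summary(a, "avg_pid"), 75)
  expect_equal(aln_summary(mk_aln(s1 = "ACGT", s2 = "ACGT"), "avg_pid"), 100)
  # gapped columns excluded from both numerator and denominator
  expect_equal(aln_summary(mk_aln(s1 = "AC-T", s2 = "ACGT"), "avg_pid"), 100)
  expect_error(aln_summary(mk_aln(s1 = "ACGT"), "avg_pid"), "2 members")

  for (seed in 1:5) {
    a <- rand_gapped_aln(5L, 40L, seed)
    expect_equal(aln_summary(a, "avg_pid"), oracle_avg_pid(a))
  }
})

test_that("slicing selects inclusive column ranges", {
  a <- as_alignment(make_seq_set(3L, 30L, seed = 1L))
  expect_equal(aln_width(slice_alignment(a, 10, 20)), 11L)
  expect_equal(biofilters:::seq_strings(slice_alignment(a, 1, 30)),
               biofilters:::seq_strings(a))

  # split/join property
  left <- slice_alignment(a, 1, 13)
  right <- slice_alignment(a, 14, 30)
  expect_equal(biofilters:::seq_strings(concat_alignments(list(left, right))),
               biofilters:::seq_strings(a))

  expect_equal(parse_slice("-,20", 30L), c(1L, 20L))
  expect_equal(parse_slice("20,-", 30L), c(20L, 30L))
  expect_equal(parse_slice("-,-", 30L), c(1L, 30L))
  expect_error(slice_alignment(a, 10, 31), "length 30")
})

test_that("member pick/delete keeps alignment length", {
  a <- as_alignment(make_seq_set(3L, 20L, seed = 2L))
  picked <- filter_members(a, c("seq1", "seq3"), "pick")
  expect_equal(biofilters:::seq_ids(picked), c("seq1", "seq3"))
  expect_equal(aln_width(picked), 20L)
  deleted <- filter_members(a, "seq2", "delete")
  expect_equal(biofilters:::seq_ids(deleted), c("seq1", "seq3"))
  expect_equal(biofilters:::seq_strings(picked), biofilters:::seq_strings(deleted))
  expect_error(filter_members(a, "ghost", "pick"), "ghost")
})

test_that("concatenation requires identical id sets and sums lengths", {
  a <- as_alignment(make_seq_set(3L, 10L, seed = 3L))
  b <- as_alignment(make_seq_set(3L, 15L, seed = 4L))
  ab <- concat_alignments(list(a, b))
  expect_equal(aln_width(ab), 25L)
  expect_equal(biofilters:::seq_strings(concat_alignments(list(a))),
               biofilters:::seq_strings(a))
  # slicing at the recorded boundary recovers the inputs
  expect_equal(biofilters:::seq_strings(slice_alignment(ab, 1, 10)),
               biofilters:::seq_strings(a))
  expect_equal(biofilters:::seq_strings(slice_alignment(ab, 11, 25)),
               biofilters:::seq_strings(b))

  c_aln <- as_alignment(seq_set(list(seq_record("other", "ACGTACGTAC"))))
  expect_error(concat_alignments(list(a, c_aln)), "other")
})

test_that("pep2dna expands residues to codons and gaps to ---", {
  cds <- seq_set(list(seq_record("p1", "ATGAAA")))
  out <- pep2dna(mk_aln(p1 = "M-K"), cds)
  expect_equal(out[[1]]$seq, "ATG---AAA")
  expect_equal(aln_width(out), 9L)

  # terminal stop in the CDS is tolerated and dropped
  cds_stop <- seq_set(list(seq_record("p1", "ATGAAATAA")))
  expect_equal(pep2dna(mk_aln(p1 = "MK"), cds_stop)[[1]]$seq, "ATGAAA")

  expect_error(pep2dna(mk_aln(p2 = "MK"), cds), "p2")
  bad <- seq_set(list(seq_record("p1", "ATGCCC")))
  expect_error(pep2dna(mk_aln(p1 = "MK"), bad), "residue 2")
})

test_that("pep2dna round-trips on random CDS/protein-alignment pairs", {
  for (seed in 1:20) {
    cds <- make_cds_set(n_seqs = 4L, seq_length = 36L, seed = seed,
                        prefix = "g")
    peps <- translate(cds, 1)
    # introduce a shared gap block so the alignment is genuinely gapped
    gapped <- lapply(seq_along(peps), function(i) {
      r <- peps[[i]]
      pos <- (seed + i) %% nchar(r$seq) + 1L
      seq_record(r$id, paste0(substr(r$seq, 1, pos - 1), "-",
                              substr(r$seq, pos, nchar(r$seq))))
    })
    paln <- as_alignment(seq_set(gapped))
    codon <- pep2dna(paln, cds)
    expect_equal(aln_width(codon), 3L * aln_width(paln))
    expect_equal(aln_width(codon) %% 3L, 0L)
    back <- translate(degap(codon), 1)
    expect_equal(biofilters:::seq_strings(back),
                 biofilters:::seq_strings(degap(paln)))
  }
})

test_that("bootstrap resamples columns with replacement, seeded", {
  one <- mk_aln(a = "A", b = "C")
  expect_equal(biofilters:::seq_strings(aln_bootstrap(one, seed = 1)),
               biofilters:::seq_strings(one))

  a <- as_alignment(make_seq_set(4L, 50L, seed = 5L))
  b1 <- aln_bootstrap(a, seed = 99)
  b2 <- aln_bootstrap(a, seed = 99)
  expect_identical(write_alignment(b1, "fasta"), write_alignment(b2, "fasta"))
  expect_equal(biofilters:::seq_ids(b1), biofilters:::seq_ids(a))

  # every drawn column is a column of the input
  cols_of <- function(x) apply(biofilters:::aln_matrix(x), 2L, paste,
                               collapse = "")
  expect_true(all(cols_of(b1) %in% cols_of(a)))
})

test_that("shuffle_sites permutes intact columns", {
  one <- mk_aln(a = "A", b = "C")
  expect_equal(biofilters:::seq_strings(shuffle_sites(one, seed = 1)),
               biofilters:::seq_strings(one))

  a <- rand_gapped_aln(4L, 60L, seed = 6L)
  sh <- shuffle_sites(a, seed = 7)
  cols_of <- function(x) sort(apply(biofilters:::aln_matrix(x), 2L, paste,
                                    collapse = ""))
  expect_equal(cols_of(sh), cols_of(a))        # column multiset preserved
  for (id in biofilters:::seq_ids(a)) {        # per-member residue multiset
    expect_equal(sort(strsplit(biofilters:::seq_strings(sh)[[id]], "")[[1]]),
                 sort(strsplit(biofilters:::seq_strings(a)[[id]], "")[[1]]))
  }
})

test_that("mutate_sites hits non-gap residues at the given rate", {
  a <- rand_gapped_aln(3L, 40L, seed = 8L)
  expect_equal(biofilters:::seq_strings(mutate_sites(a, 0, seed = 1)),
               biofilters:::seq_strings(a))

  m_in <- biofilters:::aln_matrix(a)
  m_out <- biofilters:::aln_matrix(mutate_sites(a, 1, seed = 2))
  nongap <- m_in != "-"
  expect_true(all(m_out[nongap] != m_in[nongap]))
  expect_true(all(m_out[!nongap] == "-"))
  expect_error(mutate_sites(a, 1.5), "\\[0, 1\\]")
  expect_error(mutate_sites(mk_aln(p = "MKL"), 0.5), "nucleotide")
})

test_that("all alignment operations preserve the equal-length invariant", {
  a <- rand_gapped_aln(5L, 30L, seed = 9L)
  outs <- list(slice_alignment(a, 2, 20),
               filter_members(a, "seq1", "delete"),
               aln_bootstrap(a, seed = 1),
               shuffle_sites(a, seed = 1),
               mutate_sites(a, 0.3, seed = 1))
  for (o in outs) {
    lens <- vapply(o, function(r) nchar(r$seq), integer(1L))
    expect_length(unique(lens), 1L)
  }
})
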