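test_that("NEXUS character matrices round-trip, including interleaved input", {
  nex <- paste(
    "#NEXUS",
    "BEGIN DATA;",
    "DIMENSIONS NTAX=2 NCHAR=2;",
    "FORMAT SYMBOLS=\"01\" MISSING=? GAP=-;",
    "MATRIX",
    "  taxA 01",
    "  'tax B' ?1",
    ";",
    "END;", sep = "\n")
  m <- read_character_matrix(nex)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(unclass(m)[1, ]), c("0", "1"))
  expect_equal(unname(unclass(m)[2, ]), c("?", "1"))
  expect_equal(rownames(m), c("taxA", "tax_B"))

  inter <- paste(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "DIMENSIONS NCHAR=4 NTAX=2;",
    "FORMAT SYMBOLS=\"01\" MISSING=? GAP=- INTERLEAVE;",
    "MATRIX",
    "taxA 01",
    "taxB 10",
    "",
    "taxA 1-",
    "taxB 0?",
    ";",
    "END;", sep = "\n")
  mi <- read_character_matrix(inter)
  expect_equal(unname(unclass(mi)["taxA", ]), c("0", "1", "1", "?"))
  expect_equal(unname(unclass(mi)["taxB", ]), c("1", "0", "0", "?"))

  for (rep in 1:5) {
    set.seed(100 + rep)
    rm <- random_matrix(sample(3:8, 1), sample(2:12, 1), k = sample(2:3, 1))
    back <- read_character_matrix(write_character_matrix(rm))
    expect_equal(unname(unclass(back)), unname(unclass(rm)))
    expect_equal(rownames(back), rownames(rm))
  }
})

test_that("malformed NEXUS input is rejected with informative errors", {
  expect_error(read_character_matrix("BEGIN DATA; no header"), "NEXUS")
  ragged <- paste(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=3;",
    "FORMAT MISSING=?;", "MATRIX", "taxA 010", "taxB 01", ";", "END;",
    sep = "\n")
  expect_error(read_character_matrix(ragged), "ragged|taxa")
  undeclared <- paste(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=2;",
    "FORMAT SYMBOLS=\"01\" MISSING=?;", "MATRIX", "taxA 01", "taxB 2?",
    ";", "END;", sep = "\n")
  expect_error(read_character_matrix(undeclared), "undeclared.*taxB")
  expect_error(character_matrix(matrix("0", 2, 1,
    dimnames = list(c("a", "a"), NULL))), "duplicate")
})

test_that("trees parse from Newick and NEXUS and round-trip", {
  tr <- read_tree("((A,B),(C,D));")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  expect_null(tr$edge.length)

  tr2 <- read_tree("((A:1,B:1):1,C:2);")
  expect_equal(sort(tr2$edge.length), c(1, 1, 1, 2))

  expect_error(read_tree("((A,B),(C,D);"), "parse")
  expect_error(read_tree("((A,B),(A,C));"), "duplicate")

  for (rep in 1:5) {
    set.seed(rep)
    tr3 <- ape::rtree(6)
    back <- read_tree(write_tree(tr3))
    expect_same_topology(back, tr3)
    expect_equal(sort(back$edge.length), sort(tr3$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("nucleotide recoding maps bases to digits and ambiguity to missing", {
  al <- nt_alignment(c(s1 = "ACGT", s2 = "RN-a", s3 = "ugtc"))
  rc <- recode_nucleotides(al)
  expect_equal(unname(unclass(rc)["s1", ]), c("0", "1", "2", "3"))
  expect_equal(unname(unclass(rc)["s2", ]), c("?", "?", "?", "0"))
  expect_equal(unname(unclass(rc)["s3", ]), c("3", "2", "3", "1"))

  empty <- nt_alignment(c(a = "", b = ""))
  expect_equal(ncol(recode_nucleotides(empty)), 0L)

  bad <- nt_alignment(c(s1 = "AC!T"))
  expect_error(recode_nucleotides(bad), "non-IUPAC.*site 3")
})

test_that("concatenation preserves partitions, fills missing, and is associative", {
  a <- character_matrix(matrix(c("0", "1"), 2, 1,
                               dimnames = list(c("x", "y"), NULL)))
  b <- character_matrix(matrix(c("1", "1", "0", "0"), 2, 2,
                               dimnames = list(c("x", "z"), NULL)))
  cc <- concatenate_matrices(list(mor = a, mol = b), policy = "union")
  expect_equal(ncol(cc), 3L)
  expect_equal(sort(rownames(cc)), c("x", "y", "z"))
  expect_equal(unname(unclass(cc)["y", 2:3]), c("?", "?")) # y absent in b
  expect_equal(unname(unclass(cc)["z", 1]), "?")
  expect_equal(names(partitions_of(cc)), c("mor", "mol"))

  ci <- concatenate_matrices(list(a, b), policy = "intersection")
  expect_equal(rownames(ci), "x")

  # associativity of the resulting cells
  d <- character_matrix(matrix(c("0", "0"), 2, 1,
                               dimnames = list(c("x", "y"), NULL)))
  left <- concatenate_matrices(list(
    ab = concatenate_matrices(list(a = a, b = b)), d = d))
  right <- concatenate_matrices(list(
    a = a, bd = concatenate_matrices(list(b = b, d = d))))
  common <- sort(rownames(left))
  expect_equal(unname(unclass(left)[common, ]),
               unname(unclass(right)[common, ]))
})

test_that("matrix summaries count patterns per partition and missing cells", {
  m <- character_matrix(
    rbind(t1 = c("a", "a", "g"), t2 = c("a", "a", "t")),
    partitions = list(all = 1:3))
  sm <- summarize_matrix(m)
  expect_equal(sm$distinct_patterns_total, 2L)
  expect_equal(sm$n_taxa, 2L)

  m2 <- character_matrix(rbind(t1 = c("0", "?"), t2 = c("1", "0")))
  expect_equal(summarize_matrix(m2)$missing_fraction, 0.25)

  # pattern counts are per-partition then summed: the same column content
  # in different partitions counts once per partition
  m3 <- character_matrix(
    rbind(t1 = c("0", "0", "0", "0"), t2 = c("1", "1", "1", "1")),
    partitions = list(p1 = 1:2, p2 = 3:4))
  expect_equal(summarize_matrix(m3)$distinct_patterns_total, 2L)
  expect_equal(unname(summarize_matrix(m3)$distinct_patterns), c(1L, 1L))

  # invariance under consistent taxon reordering
  set.seed(42)
  rm <- random_matrix(6, 10, k = 3)
  perm <- sample(nrow(rm))
  rm2 <- character_matrix(unclass(rm)[perm, , drop = FALSE])
  expect_equal(summarize_matrix(rm2)$distinct_patterns_total,
               summarize_matrix(rm)$distinct_patterns_total)
})

test_that("FASTA alignments read and CHARSET partitions are honoured", {
  fa <- ">s1\nACGT\nACGT\n>s2\nTTTT\nCCCC\n"
  al <- read_alignment(fa)
  expect_equal(dim(al), c(2L, 8L))
  expect_equal(paste(unclass(al)["s1", ], collapse = ""), "acgtacgt")

  nex <- paste(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=4;",
    "FORMAT SYMBOLS=\"01\" MISSING=?;", "MATRIX",
    "taxA 0101", "taxB 1010", ";", "END;",
    "BEGIN SETS;", "charset left = 1-2;", "charset right = 3-4;", "END;",
    sep = "\n")
  m <- read_character_matrix(nex)
  expect_equal(names(partitions_of(m)), c("left", "right"))
  expect_equal(partitions_of(m)$right, 3:4)
})
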