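# SAT document model: parsing, serialization, lifting, AGP/FASTA emission.

doc_fields <- c("contigs", "links", "paths", "members", "sets", "current")

test_that("minimal S record parses without sequence", {
  doc <- read_sat("S\tctg1\t9")
  expect_equal(doc$contigs$id, "ctg1")
  expect_equal(doc$contigs$length, 9)
  expect_null(doc$sequences)
})

test_that("malformed records report the line number", {
  expect_error(read_sat(c("S\tctg1\t9", "S\tctg2")), "line 2")
  expect_error(read_sat("L\tctg1\t+\tctg2\tx\twt:f:1"), "line 1")
  expect_error(read_sat("Q\tfoo"), "unknown record type")
  expect_error(read_sat(c("S\tA\t5", "P\tp1\t5\tB+")), "unknown contig")
})

test_that("empty document writes a lone C record and round-trips", {
  doc <- sat_document(contigs = data.frame(id = character(0),
                                           length = numeric(0)))
  lines <- format_sat(doc)
  expect_equal(lines, "C\tasm1")
  doc2 <- read_sat(lines)
  expect_equal(doc2$current, "asm1")
  expect_equal(nrow(doc2$contigs), 0)
})

test_that("link weights are carried as wt:f tags", {
  doc <- sat_from_lengths(c(A = 10, B = 20))
  doc$links <- data.frame(from = "A", from_orient = "+", to = "B",
                          to_orient = "-", weight = 2.5, tags = "",
                          stringsAsFactors = FALSE)
  lines <- format_sat(doc)
  expect_true(any(grepl("^L\tA\t\\+\tB\t-\twt:f:2.5$", lines)))
  expect_equal(read_sat(lines)$links$weight, 2.5)
})

test_that("the worked-example document has 11 S, 5 L and 6 P records", {
  wx <- worked_example()
  doc <- sat_from_lengths(wx$lengths)
  paths <- extract_scaffold_paths(
    prune_scaffold_graph(build_scaffold_graph(wx$neighbors)))
  doc <- compact_sat(compose_scaffolds(doc, paths))
  lines <- format_sat(doc)
  expect_equal(sum(startsWith(lines, "S\t")), 11)
  expect_equal(sum(startsWith(lines, "L\t")), 5)
  expect_equal(sum(startsWith(lines, "P\t")), 6)
  parsed <- read_sat(lines)
  expect_equal(nrow(parsed$contigs), 11)
  expect_equal(nrow(parsed$links), 5)
  expect_equal(nrow(parsed$paths), 6)
  # golden-file byte identity: write -> parse -> write
  f <- withr::local_tempfile(fileext = ".sat")
  write_sat(doc, f)
  f2 <- withr::local_tempfile(fileext = ".sat")
  write_sat(read_sat(f), f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("write-then-parse is the identity on random documents", {
  set.seed(42)
  for (i in 1:50) {
    doc <- random_sat_doc(sample(3:12, 1))
    doc2 <- read_sat(format_sat(doc), gap_len = doc$gap_len)
    expect_equal(doc2[doc_fields], doc[doc_fields])
  }
})

test_that("unknown optional tags survive a round trip", {
  lines <- c("S\tA\t5\tab:Z:hello\tnm:i:3", "S\tB\t4")
  doc <- read_sat(lines)
  expect_equal(doc$contigs$tags[1], "ab:Z:hello\tnm:i:3")
  expect_identical(format_sat(doc)[1], lines[1])
})

test_that("coordinate lifting follows member orientation", {
  # single-contig path: identity
  doc <- sat_from_lengths(c(A = 100))
  expect_equal(lift_position(doc, "A", 0),
               data.frame(scaffold = "A", position = 0, strand = "+",
                          stringsAsFactors = FALSE))
  # path [A+ (100), B- (50)], gap 200: lift(B, 0) -> 100+200+(50-1-0) = 349
  doc <- sat_from_lengths(c(A = 100, B = 50))
  doc <- compose_scaffolds(doc, list(list(
    members = data.frame(contig = c("A", "B"), orient = c("+", "-"),
                         stringsAsFactors = FALSE),
    cyclic = FALSE, weights = 1)))
  lp <- lift_position(doc, "B", 0)
  expect_equal(lp$position, 349)
  expect_equal(lp$strand, "-")
  expect_error(lift_position(doc, "Z", 0), "not in any current path")
  expect_error(lift_position(doc, "A", 100), "outside contig")
})

test_that("lifting is a bijection onto non-gap scaffold bases", {
  doc <- sat_from_lengths(c(A = 5, B = 4, C = 3), gap_len = 2)
  doc <- compose_scaffolds(doc, list(list(
    members = data.frame(contig = c("A", "B", "C"),
                         orient = c("+", "-", "+"), stringsAsFactors = FALSE),
    cyclic = FALSE, weights = c(1, 1))))
  hits <- unlist(lapply(c("A", "B", "C"), function(ctg) {
    len <- c(A = 5, B = 4, C = 3)[[ctg]]
    lift_position(doc, ctg, 0:(len - 1))$position
  }))
  expect_equal(length(hits), length(unique(hits)))
  gap_bases <- c(5, 6, 11, 12)  # two 2-base gaps
  expect_setequal(hits, setdiff(0:15, gap_bases))
})

test_that("lifting composes across two scaffolding rounds", {
  doc1 <- sat_from_lengths(c(A = 100, B = 50, C = 70), gap_len = 10)
  doc1 <- compose_scaffolds(doc1, list(
    list(members = data.frame(contig = c("A", "B"), orient = c("+", "-"),
                              stringsAsFactors = FALSE),
         cyclic = FALSE, weights = 1),
    list(members = data.frame(contig = "C", orient = "+",
                              stringsAsFactors = FALSE),
         cyclic = FALSE, weights = numeric(0))))
  p1 <- current_paths(doc1)[startsWith(current_paths(doc1), "u")]
  doc2 <- compose_scaffolds(doc1, list(list(
    members = data.frame(contig = c(p1, "C"), orient = c("+", "+"),
                         stringsAsFactors = FALSE),
    cyclic = FALSE, weights = 1)))
  # direct lift through the composed document
  direct <- lift_position(doc2, "B", 7)
  # manual two-step: B in [A+,B-] then that scaffold (+) into the final one
  step1_pos <- 100 + 10 + (50 - 1 - 7)
  expect_equal(direct$position, step1_pos)  # first block starts at offset 0
  expect_equal(direct$strand, "-")
  direct_c <- lift_position(doc2, "C", 3)
  expect_equal(direct_c$position, (100 + 10 + 50) + 10 + 3)
})

test_that("AGP output is contiguous, 1-based and orientation-faithful", {
  doc <- sat_from_lengths(c(A = 100))
  agp <- sat_to_agp(doc)
  expect_equal(nrow(agp), 1)
  expect_equal(agp$object_beg, 1)
  expect_equal(agp$object_end, 100)
  expect_equal(agp$component_type, "W")

  doc <- sat_from_lengths(c(A = 100, B = 50))
  doc <- compose_scaffolds(doc, list(list(
    members = data.frame(contig = c("A", "B"), orient = c("+", "-"),
                         stringsAsFactors = FALSE),
    cyclic = FALSE, weights = 1)))
  agp <- sat_to_agp(doc, gap_len = 200)
  expect_equal(agp$object_beg, c(1, 101, 301))
  expect_equal(agp$object_end, c(100, 300, 350))
  expect_equal(agp$component_type, c("W", "U", "W"))
  expect_equal(agp$orientation, c("+", "proximity_ligation", "-"))
  expect_equal(agp$component_id[2], "200")

  set.seed(9)
  for (i in 1:20) {
    doc <- random_sat_doc(sample(3:10, 1))
    agp <- sat_to_agp(doc)
    for (p in unique(agp$object)) {
      sub <- agp[agp$object == p, ]
      expect_equal(sub$object_beg[1], 1)
      if (nrow(sub) > 1)
        expect_equal(sub$object_beg[-1], sub$object_end[-nrow(sub)] + 1)
      expect_equal(max(sub$object_end),
                   doc$paths$length[doc$paths$id == p])
    }
  }
})

test_that("scaffold FASTA concatenates, reverse-complements and gaps", {
  seqs <- c(A = "ACGTACGT", B = "GGCC")
  doc <- sat_from_lengths(c(A = 8, B = 4), sequences = seqs, gap_len = 2)
  fa <- scaffold_fasta(doc)
  expect_equal(as.character(fa[["A"]]), "ACGTACGT")
  doc <- compose_scaffolds(doc, list(list(
    members = data.frame(contig = c("A", "B"), orient = c("+", "-"),
                         stringsAsFactors = FALSE),
    cyclic = FALSE, weights = 1)))
  fa <- scaffold_fasta(doc)
  expect_equal(as.character(fa[[1]]), "ACGTACGTNNGGCC")  # revcomp(GGCC)=GGCC
  expect_equal(unname(Biostrings::width(fa)),
               unname(doc$paths$length[match(names(fa), doc$paths$id)]))
  doc$sequences <- doc$sequences["A"]
  expect_error(scaffold_fasta(doc), "missing sequence for contig: B")
})

test_that("scaffold lengths conserve contig lengths plus gaps", {
  set.seed(5)
  for (i in 1:20) {
    doc <- random_sat_doc(sample(4:12, 1))
    cur <- current_paths(doc)
    plen <- doc$paths$length[match(cur, doc$paths$id)]
    n_members <- sum(doc$members$path %in% cur)
    expect_equal(sum(plen),
                 sum(doc$contigs$length) +
                   doc$gap_len * (n_members - length(cur)))
  }
})

test_that("contiguity metrics match their definitions", {
  expect_equal(assembly_metrics(10)$n50, 10)
  m <- assembly_metrics(c(5, 4, 3, 2, 1))
  expect_equal(m$n50, 4)  # cumulative 5,9 >= 7.5 at the second length
  expect_equal(m$largest, 5)
  expect_equal(m$count, 5)
  expect_equal(assembly_metrics(c(5, 4, 3, 2, 1), genome_size = 15)$ng50, 4)
})
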