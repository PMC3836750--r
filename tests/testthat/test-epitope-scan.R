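# Linear / conformational epitope scanning against human template sets.

test_that("rat-unique calls match the membership definition", {
  # query equal to one template: nothing is rat-unique
  n <- 30
  withr::with_seed(41, ch <- toy_chain(n))
  set <- template_set(c("t1", "t2"),
                      c(ch$sequence, paste(rep("A", n), collapse = "")))
  m <- identity_mapping(n)
  expect_equal(nrow(rat_unique_positions(ch, m, set)), 0)

  # definitional toy: column 5 profile {S,S,S}, query has A
  q <- parse_chain("AAAAATTTTT", "L")
  q <- delimit_regions(q, "imgt", region_map = tibble::tibble(
    position = 1:10, region = rep(c("FR1", "CDR1"), c(8, 2))
  ))
  tem <- rep("AAAASTTTTT", 3)
  set2 <- template_set(paste0("t", 1:3), tem)
  ru <- rat_unique_positions(q, identity_mapping(10), set2)
  expect_equal(ru$position, 5L)
  expect_equal(ru$aa, "A")
})

test_that("rat-unique calls equal the brute-force membership oracle", {
  withr::with_seed(43, {
    for (i in 1:6) {
      ch <- toy_chain(30)
      set <- toy_set(ch$sequence, n_templates = 5, p_mut = 0.3, p_gap = 0.1)
      got <- rat_unique_positions(ch, identity_mapping(30), set)$position
      expect_equal(got, oracle_rat_unique(ch$sequence,
                                          fr_positions(ch), set))
    }
  })
})

test_that("unmapped framework positions raise an error listing them", {
  ch <- toy_chain(30, seq = paste(rep("A", 30), collapse = ""))
  part <- abscan:::new_query_mapping(
    tibble::tibble(query_position = 3:30, column = 3:30), "toy", "L"
  )
  set <- template_set("t", paste(rep("A", 30), collapse = ""))
  expect_error(rat_unique_positions(ch, part, set), "1, 2")
})

test_that("a planted rat-unique residue yields exactly the covering windows", {
  # 25-residue single FR, planted mismatch at position 12; expected
  # windows enumerated by the brute-force oracle
  n <- 25
  withr::with_seed(47, ch <- toy_chain(n, blocks = c(FR1 = n)))
  tmpl <- ch$sequence
  substr(tmpl, 12, 12) <- setdiff(toy_alphabet,
                                  substr(ch$sequence, 12, 12))[1]
  set <- template_set(c("t1", "t2"), c(tmpl, tmpl))
  m <- identity_mapping(n)
  got <- linear_scan(ch, m, set)
  oracle <- oracle_linear_windows(ch$sequence, region_map(ch), set)
  expect_equal(got$window_start, oracle)
  # all windows cover position 12, bounded by 6 per side and FR edges
  expect_true(all(got$window_start <= 12 & got$window_end >= 12))
  expect_gte(nrow(got), 1)
  expect_lte(nrow(got), 6)
  expect_true(all(vapply(got$rat_unique, identical, logical(1), 12L)))
})

test_that("degenerate linear-scan settings behave as documented", {
  n <- 30
  withr::with_seed(48, ch <- toy_chain(n))
  set <- toy_set(ch$sequence, n_templates = 3, p_mut = 0.5)
  m <- identity_mapping(n)
  # query identical to one template: no epitopes
  set_id <- template_set(c("q", "t"), c(ch$sequence,
                                        set$templates$aligned[1]))
  expect_equal(nrow(suppressWarnings(linear_scan(ch, m, set_id))), 0)
  # vacuous mismatch allowance: no epitopes regardless of query
  cfg <- scan_config(max_mismatches = 6L)
  expect_equal(nrow(suppressWarnings(linear_scan(ch, m, set, cfg))), 0)
  # FRs shorter than the probe warn once and contribute nothing
  expect_warning(linear_scan(ch, m, set_id), "shorter than")
})

test_that("windows containing X are skipped", {
  n <- 25
  withr::with_seed(49, ch <- toy_chain(n, blocks = c(FR1 = n)))
  seq_x <- ch$sequence
  substr(seq_x, 10, 10) <- "X"
  chx <- toy_chain(n, blocks = c(FR1 = n), seq = seq_x)
  # templates disagree everywhere: every scanned window is an epitope
  set <- template_set("t", paste(rep("G", n), collapse = ""))
  got <- linear_scan(chx, identity_mapping(n), set)
  expect_false(any(got$window_start <= 10 & got$window_end >= 10))
  # and X positions are never rat-unique
  expect_false(10L %in% rat_unique_positions(chx, identity_mapping(n),
                                             set)$position)
})

test_that("linear scan equals the exhaustive oracle on random toys", {
  withr::with_seed(51, {
    for (i in 1:8) {
      n_t <- sample(2:6, 1)
      ch <- toy_chain(30)
      set <- toy_set(ch$sequence, n_templates = n_t, p_mut = 0.25,
                     p_gap = 0.08)
      got <- suppressWarnings(
        linear_scan(ch, identity_mapping(30), set)
      )$window_start
      expect_equal(got, oracle_linear_windows(ch$sequence, region_map(ch),
                                              set))
    }
  })
})

test_that("adding a template never enlarges scan output", {
  withr::with_seed(53, {
    for (i in 1:5) {
      ch <- toy_chain(30)
      set_small <- toy_set(ch$sequence, n_templates = 3, p_mut = 0.3)
      extra <- toy_set(ch$sequence, n_templates = 1, p_mut = 0.3)
      set_big <- template_set(
        c(set_small$templates$accession, "extra"),
        c(set_small$templates$aligned, extra$templates$aligned)
      )
      m <- identity_mapping(30)
      ru_s <- rat_unique_positions(ch, m, set_small)$position
      ru_b <- rat_unique_positions(ch, m, set_big)$position
      expect_true(all(ru_b %in% ru_s))
      lin_s <- suppressWarnings(linear_scan(ch, m, set_small))$window_start
      lin_b <- suppressWarnings(linear_scan(ch, m, set_big))$window_start
      expect_true(all(lin_b %in% lin_s))
    }
  })
})

# line of CA atoms spaced `spacing` apart along x, one residue each
line_structure <- function(n, spacing = 3.8, chain = "L") {
  structure_model(tibble::tibble(
    frame = 1L, chain = chain, resno = seq_len(n), resname = "ALA",
    elety = "CA", element = "C",
    x = spacing * seq_len(n), y = 0, z = 0
  ))
}

test_that("conformational scan applies both the distance and the human filter", {
  n <- 10
  withr::with_seed(61, ch <- toy_chain(n, blocks = c(FR1 = n)))
  m <- identity_mapping(n)

  # pair at 6.0 A minimum distance: never flagged even if rat-unique
  far <- structure_model(tibble::tibble(
    frame = 1L, chain = "L", resno = 1:10, resname = "ALA", elety = "CA",
    element = "C", x = 6 * (1:10), y = 0, z = 0
  ))
  set_none <- template_set("t", paste(rep("G", n), collapse = ""))
  got_far <- conformational_scan(far, ch, m, set_none)
  expect_equal(nrow(got_far), 0)

  # pair at 4.0 A where one template carries both residues: not flagged
  near <- structure_model(tibble::tibble(
    frame = 1L, chain = "L", resno = 1:10, resname = "ALA", elety = "CA",
    element = "C", x = 4 * (1:10), y = 0, z = 0
  ))
  set_match <- template_set("t", ch$sequence)
  expect_equal(nrow(conformational_scan(near, ch, m, set_match)), 0)
})

test_that("conformational scan equals the exhaustive oracle", {
  n <- 10
  st <- line_structure(n)
  withr::with_seed(63, {
    for (i in 1:5) {
      ch <- toy_chain(n, blocks = c(FR1 = n))
      set <- toy_set(ch$sequence, n_templates = 3, p_mut = 0.4)
      got <- conformational_scan(st, ch, identity_mapping(n), set)
      coords <- lapply(setNames(1:n, 1:n), function(r) {
        matrix(c(3.8 * r, 0, 0), 1)
      })
      oracle <- oracle_conformational(ch$sequence, 1:n, set, coords)
      expect_equal(nrow(got), length(oracle))
      if (length(oracle)) {
        expect_equal(
          unname(as.matrix(got[, c("position_a", "position_b")])),
          do.call(rbind, oracle)
        )
      }
    }
  })
})

test_that("conformational scan errors when residues are missing", {
  ch <- toy_chain(10, blocks = c(FR1 = 10),
                  seq = paste(rep("A", 10), collapse = ""))
  st <- line_structure(8)
  set <- template_set("t", paste(rep("A", 10), collapse = ""))
  expect_error(conformational_scan(st, ch, identity_mapping(10), set),
               "9, 10")
})

test_that("substitution proposals take the column consensus", {
  # linear-only position whose column profile is {S:12, T:8} -> S
  n <- 30
  ch <- toy_chain(n, seq = paste(rep("A", n), collapse = ""))
  seqs <- c(rep(sub("^A", "S", ch$sequence), 12),
            rep(sub("^A", "T", ch$sequence), 8))
  set <- template_set(sprintf("t%02d", 1:20), seqs)
  m <- identity_mapping(n)
  lin <- suppressWarnings(linear_scan(ch, m, set))
  tab <- propose_substitutions(
    lin, tibble::tibble(chain = character(), position_a = integer(),
                        position_b = integer()),
    set, m, ch
  )
  expect_equal(tab$position, 1L)
  expect_equal(tab$rat_aa, "A")
  expect_equal(tab$human_aa, "S")
  expect_equal(tab$provenance, "linear")
})

test_that("empty scans yield an empty table; shared positions are 'both'", {
  n <- 30
  withr::with_seed(71, ch <- toy_chain(n))
  set <- template_set(c("a", "b"), c(ch$sequence, ch$sequence))
  m <- identity_mapping(n)
  empty <- propose_substitutions(
    suppressWarnings(linear_scan(ch, m, set)),
    tibble::tibble(chain = character(), position_a = integer(),
                   position_b = integer()),
    set, m, ch
  )
  expect_equal(nrow(empty), 0)

  # engineer 3 linear-only + 1 shared position: plant rat-unique residues
  # at 2,3,4 (linear) and 20 (linear + conformational via a close pair)
  fx <- make_sequence_fixture(
    seed = 72,
    planted_unique = tibble::tibble(chain = "L",
                                    position = c(2L, 3L, 4L, 20L))
  )
  rmap <- region_map_table(fx$chains["L"], "imgt")
  st <- make_structure_fixture(seed = 73, region_map = rmap)
  lin <- linear_scan(fx$chains$L, fx$mappings$L, fx$templates$L)
  conf <- conformational_scan(st$reference, fx$chains$L, fx$mappings$L,
                              fx$templates$L)
  tab <- propose_substitutions(lin, conf, fx$templates$L, fx$mappings$L,
                               fx$chains$L)
  expect_equal(tab$position, c(2L, 3L, 4L, 20L))
  expect_true(all(tab$provenance[1:3] %in% c("linear", "both")))
  # soundness: every proposed position re-checks as rat-unique
  ru <- rat_unique_positions(fx$chains$L, fx$mappings$L, fx$templates$L)
  expect_true(all(tab$position %in% ru$position))
  expect_true(all(tab$rat_aa != tab$human_aa))
})

test_that("consensus ties break alphabetically and all-gap columns skip", {
  n <- 30
  ch <- toy_chain(n, seq = paste(rep("A", n), collapse = ""))
  # column 1: T and S once each -> alphabetical tie-break picks S
  seqs <- c(sub("^A", "T", ch$sequence), sub("^A", "S", ch$sequence))
  set <- template_set(c("a", "b"), seqs)
  m <- identity_mapping(n)
  lin <- suppressWarnings(linear_scan(ch, m, set))
  tab <- propose_substitutions(
    lin, tibble::tibble(chain = character(), position_a = integer(),
                        position_b = integer()),
    set, m, ch
  )
  expect_equal(tab$human_aa, "S")

  # all-gap column: position skipped with a warning
  seqs2 <- c(sub("^A", "-", ch$sequence), sub("^A", "-", ch$sequence))
  set2 <- template_set(c("a", "b"), seqs2)
  lin2 <- suppressWarnings(linear_scan(ch, m, set2))
  expect_warning(
    tab2 <- propose_substitutions(
      lin2, tibble::tibble(chain = character(), position_a = integer(),
                           position_b = integer()),
      set2, m, ch
    ),
    "all-gap"
  )
  expect_false(1L %in% tab2$position)
})

test_that("substitution tables round-trip through TSV in canonical order", {
  tab <- tibble::tibble(
    chain = c("H", "L", "L"), position = c(5L, 9L, 2L),
    rat_aa = c("A", "A", "G"), human_aa = c("S", "S", "D"),
    provenance = "linear"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_substitution_table(tab, path)
  back <- read_substitution_table(path)
  expect_equal(back$chain, c("L", "L", "H"))
  expect_equal(back$position, c(2L, 9L, 5L))
  dup <- tab
  dup$position <- c(5L, 9L, 9L)
  expect_error(write_substitution_table(dup, path), "duplicate")
})
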