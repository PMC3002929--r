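#' The 29 recurrent TP53 hotspot codons
#'
#' The catalog of the 29 most recurrently mutated TP53 codons used for
#' hotspot calling: a missense change is a hotspot mutation iff its
#' reference amino acid and codon match one of these entries.
#'
#' @return data frame with columns `ref_aa`, `codon` (29 rows).
#' @export
tp53_hotspots <- function() {
  spots <- c("K132", "C135", "P151", "V157", "R158", "Y163", "V173", "R175",
             "C176", "H179", "H193", "Y205", "Y220", "Y234", "M237", "C238",
             "S241", "C242", "G245", "M246", "R248", "R249", "G266", "R273",
             "P278", "R280", "D281", "R282", "E285")
  data.frame(ref_aa = substr(spots, 1, 1),
             codon = as.integer(substring(spots, 2)),
             stringsAsFactors = FALSE)
}

.mutation_kinds <- c("missense", "nonsense", "frameshift_ins",
                     "frameshift_del", "inframe_ins", "inframe_del",
                     "splice", "wild_type", "not_sequenced")

.mk_record <- function(kind, codon = NA_integer_, ref_aa = NA_character_,
                       alt_aa = NA_character_, raw_token = NA_character_) {
  data.frame(kind = kind, codon = as.integer(codon), ref_aa = ref_aa,
             alt_aa = alt_aa, raw_token = raw_token, stringsAsFactors = FALSE)
}

.first_int <- function(s) {
  m <- regmatches(s, regexpr("[0-9]+", s))
  if (length(m)) as.integer(m) else NA_integer_
}

.parse_mutation_token <- function(tok) {
  t0 <- trimws(gsub("\\s+", " ", tok))
  if (!nzchar(t0)) .stopf("cannot parse empty mutation token")
  low <- tolower(t0)
  if (low %in% c("wild type", "wildtype", "wt"))
    return(.mk_record("wild_type", raw_token = t0))
  if (t0 == "NA" || low == "not sequenced")
    return(.mk_record("not_sequenced", raw_token = t0))
  if (grepl("splice", low, fixed = TRUE) || grepl("IVS", t0, fixed = TRUE))
    return(.mk_record("splice",
                      codon = if (grepl("^[0-9]", t0)) .first_int(t0) else NA,
                      raw_token = t0))
  if (grepl("ins|del", low)) {
    m <- regexec("(ins|del)\\s*([ACGT]+)$", t0)
    hit <- regmatches(t0, m)[[1]]
    codon <- .first_int(t0)
    if (is.na(codon)) .stopf("cannot parse mutation token: '%s'", t0)
    if (length(hit)) { # nucleotide payload: frame from payload length
      op <- hit[2]
      frame_ok <- nchar(hit[3]) %% 3 == 0
      kind <- paste0(if (frame_ok) "inframe_" else "frameshift_", op)
      return(.mk_record(kind, codon = codon, raw_token = t0))
    }
    # codon-range or single-codon indel ("del 155-156", "155_156del",
    # "del 255"): whole codons, so in frame
    op <- if (grepl("ins", low)) "inframe_ins" else "inframe_del"
    return(.mk_record(op, codon = codon, raw_token = t0))
  }
  compact <- gsub(" ", "", t0, fixed = TRUE)
  if (grepl("^[A-Z][0-9]+[A-Z]$", compact)) {
    ref <- substr(compact, 1, 1)
    alt <- substr(compact, nchar(compact), nchar(compact))
    codon <- .first_int(compact)
    kind <- if (alt == "X") "nonsense" else "missense"
    return(.mk_record(kind, codon = codon, ref_aa = ref, alt_aa = alt,
                      raw_token = t0))
  }
  .stopf("cannot parse mutation token: '%s'", t0)
}

#' Parse a TP53 mutation string
#'
#' Understands the compact sequencing-report dialect of clinical TP53
#' tables: `"wild type"`; `"NA"` (not sequenced); protein changes
#' `RefPosAlt` (`"G266E"`, nonsense when Alt is `X` as in `"R213X"`);
#' nucleotide insertions/deletions whose payload length sets the frame
#' (`"239 insT"` is a 1-nt frameshift, `"218delGTG"` a 3-nt in-frame
#' deletion); whole-codon deletions (`"del 155-156"`, `"155_156del"`,
#' `"del 255"`), which are in-frame; and splice-site changes marked by
#' `"splice"` or intronic `IVS` nomenclature. Comma-separated lists yield
#' one record per mutation. Unparseable tokens raise an error naming the
#' token; nothing is silently skipped.
#'
#' @param raw non-empty mutation string, possibly comma-separated.
#' @return data frame with one row per mutation: `kind`, `codon`,
#'   `ref_aa`, `alt_aa`, `raw_token`.
#' @export
parse_mutation <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1, nzchar(raw))
  tokens <- strsplit(raw, ",", fixed = TRUE)[[1]]
  do.call(rbind, lapply(tokens, .parse_mutation_token))
}

#' Canonical string form of a parsed mutation record
#'
#' Protein changes are rendered compactly (`"R175H"`, `"R213X"`);
#' wild-type and not-sequenced records render as `"wild type"` / `"NA"`;
#' indels and splice records keep their original token (the dialect has no
#' single canonical spelling for them). `parse -> format -> parse` is
#' stable.
#'
#' @param records data frame from [parse_mutation()].
#' @return character vector of mutation strings.
#' @export
format_mutation <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    switch(records$kind[i],
      wild_type = "wild type",
      not_sequenced = "NA",
      missense = ,
      nonsense = paste0(records$ref_aa[i], records$codon[i],
                        records$alt_aa[i]),
      records$raw_token[i])
  }, character(1))
}

#' Classify parsed mutation records
#'
#' `is_complex` marks the protein-truncating classes: nonsense, frameshift
#' and in-frame insertions/deletions, and splice mutations. `is_hotspot`
#' marks missense changes whose (reference amino acid, codon) pair is in
#' the 29-codon hotspot catalog. Wild-type and not-sequenced records get
#' all-FALSE flags.
#'
#' @param records data frame from [parse_mutation()].
#' @param hotspots hotspot catalog, default [tp53_hotspots()].
#' @return `records` with logical columns `is_complex`, `is_missense`,
#'   `is_hotspot` appended.
#' @export
classify_mutations <- function(records, hotspots = tp53_hotspots()) {
  complex_kinds <- c("nonsense", "frameshift_ins", "frameshift_del",
                     "inframe_ins", "inframe_del", "splice")
  records$is_complex <- records$kind %in% complex_kinds
  records$is_missense <- records$kind == "missense"
  key <- paste0(records$ref_aa, records$codon)
  records$is_hotspot <- records$is_missense &
    key %in% paste0(hotspots$ref_aa, hotspots$codon)
  records
}

#' Read a mutation table (one row per mutation) and parse/classify it
#'
#' Expected TSV columns: `sample_id`, `group`, `mutation`,
#' `predicted_deleterious` (TRUE/FALSE/NA; an externally supplied
#' missense-effect verdict), `abundance` (fraction of mutant allele in
#' tumor DNA, NA when not estimated). Optional columns are carried along.
#' Wild-type and not-sequenced samples appear as single rows with
#' mutation `"wild type"` / `"NA"`.
#'
#' @param path TSV path.
#' @return data frame of classified mutation records.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0),
                          colClasses = "character")
  need <- c("sample_id", "group", "mutation")
  if (!all(need %in% names(df)))
    .stopf("mutation table must have columns: %s", paste(need, collapse = ", "))
  if (is.null(df$predicted_deleterious)) df$predicted_deleterious <- "NA"
  if (is.null(df$abundance)) df$abundance <- "NA"
  parsed <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    rec <- parse_mutation(df$mutation[i])
    if (nrow(rec) != 1L)
      .stopf("row %d: one mutation per row expected, got %d", i, nrow(rec))
    rec
  }))
  out <- cbind(df[setdiff(names(df), "mutation")], parsed)
  out$predicted_deleterious <- as.logical(out$predicted_deleterious)
  out$abundance <- suppressWarnings(as.numeric(out$abundance))
  classify_mutations(out)
}

#' Path to the packaged breast-tumor TP53 mutation fixture
#'
#' Per-mutation transcription of the TP53 sequencing results of four
#' breast-tumor groups (27 BRCA1-mutated, 17 luminal-J, 21 basal-like,
#' 31 luminal-H tumors; one row per mutation plus one row per wild-type or
#' unsequenced tumor). `predicted_deleterious` encodes the published
#' SIFT / EffectGroup3 verdicts (tolerated missense = FALSE); the printed
#' per-tumor complex and hotspot flags are kept as `complex_printed` /
#' `hotspot_printed`.
#'
#' @return file path.
#' @export
tp53_fixture_path <- function() {
  system.file("extdata", "table1_mutations.tsv", package = "cnacompare",
              mustWork = TRUE)
}

#' Per-group tumor-level mutation summary
#'
#' Counts tumors, never mutations: a tumor with three complex mutations
#' contributes one. Unsequenced tumors are excluded from the denominator.
#' A mutation enters the counts only if its estimated abundance exceeds
#' `abundance_min` or is unknown (tables that already reflect the filter
#' leave abundance unset).
#'
#' @param records classified records ([read_mutation_table()] output).
#' @param group group label.
#' @param abundance_min minimum mutant-allele abundance (default 0.25).
#' @return list of tumor counts: `n_sequenced`, `n_mutated`, `n_complex`,
#'   `n_deleterious_missense`, `n_hotspot`.
#' @export
group_summary <- function(records, group, abundance_min = 0.25) {
  if (!group %in% records$group) .stopf("unknown group: %s", group)
  sub <- records[records$group == group, , drop = FALSE]
  passes <- is.na(sub$abundance) | sub$abundance > abundance_min
  per_sample <- function(cond) {
    length(unique(sub$sample_id[cond]))
  }
  sequenced_ids <- setdiff(unique(sub$sample_id),
                           unique(sub$sample_id[sub$kind == "not_sequenced"]))
  seq_ok <- sub$sample_id %in% sequenced_ids
  mut <- !(sub$kind %in% c("wild_type", "not_sequenced")) & passes & seq_ok
  list(
    group = group,
    n_sequenced = length(sequenced_ids),
    n_mutated = per_sample(mut),
    n_complex = per_sample(mut & sub$is_complex),
    n_deleterious_missense = per_sample(mut & sub$is_missense &
                                          sub$predicted_deleterious %in% TRUE),
    n_hotspot = per_sample(mut & sub$is_hotspot)
  )
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test. Under the default `"minlike"` rule the
#' p-value is the sum of the probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (with a 1e-12 relative tolerance for ties); this is the convention of
#' most statistical software. The `"central"` rule instead doubles the
#' smaller one-sided tail (capped at 1), a convention some packages use;
#' the two can differ by up to a factor of two. Any zero margin gives
#' p = 1.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @param convention `"minlike"` (default) or `"central"`.
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_tailed <- function(m, convention = c("minlike", "central")) {
  convention <- match.arg(convention)
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0), all(m == round(m)))
  if (sum(m) < 1) .stopf("grand total must be >= 1")
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  if (min(r1, r2, c1, c2) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  if (convention == "minlike") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  } else {
    lower <- sum(probs[support <= m[1, 1]])
    upper <- sum(probs[support >= m[1, 1]])
    p <- min(1, 2 * min(lower, upper))
  }
  min(p, 1)
}

#' Compare a mutation feature between two group summaries
#'
#' Builds the 2x2 table (feature-positive vs feature-negative tumors by
#' group) from two [group_summary()] results and applies
#' [fisher_exact_two_tailed()].
#'
#' @param summary_a,summary_b [group_summary()] results.
#' @param feature one of `"mutated"`, `"complex"`,
#'   `"deleterious_missense"`, `"hotspot"`.
#' @param convention passed to [fisher_exact_two_tailed()].
#' @return list with `table` (2x2 matrix, rows = groups) and `p`.
#' @export
compare_groups <- function(summary_a, summary_b,
                           feature = c("mutated", "complex",
                                       "deleterious_missense", "hotspot"),
                           convention = "minlike") {
  feature <- match.arg(feature)
  field <- paste0("n_", feature)
  tab <- matrix(c(summary_a[[field]],
                  summary_a$n_sequenced - summary_a[[field]],
                  summary_b[[field]],
                  summary_b$n_sequenced - summary_b[[field]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(summary_a$group, summary_b$group),
                                c(feature, paste0("not_", feature))))
  list(table = tab, p = fisher_exact_two_tailed(tab, convention))
}
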