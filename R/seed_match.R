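#' miRNA seed extraction
#'
#' The seed is the 5' region of the mature miRNA that nucleates target
#' recognition: nucleotides 2-7 (`"2_7"`, the 6mer core) or 2-8 (`"2_8"`,
#' the 7mer-m8 core, the default used throughout the pipeline).
#'
#' @param mir_sequence mature miRNA sequence, 5'->3'. `T` is accepted and
#'   canonicalised to `U`.
#' @param span `"2_8"` (default) or `"2_7"`.
#' @return the seed as an RNA string.
#' @export
seed_of <- function(mir_sequence, span = c("2_8", "2_7")) {
  span <- match.arg(span)
  s <- .canon_rna(mir_sequence)
  if (nchar(s) < 8) stop("miRNA sequence shorter than 8 nt")
  substr(s, 2, if (span == "2_8") 8 else 7)
}

.canon_rna <- function(x) {
  s <- chartr("tT", "uU", toupper(x))
  if (grepl("[^ACGU]", s)) stop("invalid alphabet: expected A/C/G/U (or T)")
  s
}

# reverse complement of an RNA string (the target-side match of a seed)
.rna_rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

# all (overlapping) start positions of `pattern` in `subject`, 1-based
.match_starts <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(Biostrings::RNAString(pattern),
                                             Biostrings::RNAString(subject)))
}

#' Matching rules for seed sites
#'
#' The default rule is the strict canonical one: perfect Watson-Crick
#' complementarity to miRNA positions 2-8 (a 7mer-m8 site), with G:U wobble
#' disallowed. A site is upgraded to 8mer when the target base pairing
#' opposite miRNA position 1 (immediately 3' of the core on the target) is an
#' adenine. Optional relaxations admit 6mer cores (positions 2-7), which are
#' reported as 7mer-A1 when A-anchored and 6mer otherwise.
#'
#' @param span seed span for the core match, `"2_8"` or `"2_7"`.
#' @param allow_6mer when `span = "2_7"`, also report plain 6mer sites
#'   (otherwise only A1-anchored 7mer-A1 sites count).
#' @export
site_rules <- function(span = c("2_8", "2_7"), allow_6mer = TRUE) {
  list(span = match.arg(span), allow_6mer = isTRUE(allow_6mer))
}

.site_len <- c(`6mer` = 6L, `7mer-A1` = 7L, `7mer-m8` = 7L, `8mer` = 8L)

# classify core matches at 1-based starts on `subject`; returns a data.frame
# with 1-based start, type. The A1 anchor is the base just 3' of the core.
.classify_sites <- function(subject, starts, core_len, span) {
  if (!length(starts)) {
    return(data.frame(start = integer(0), site_type = character(0)))
  }
  a1 <- substring(subject, starts + core_len, starts + core_len)
  if (span == "2_8") {
    type <- ifelse(a1 == "A", "8mer", "7mer-m8")
  } else {
    type <- ifelse(a1 == "A", "7mer-A1", "6mer")
  }
  data.frame(start = starts, site_type = type, stringsAsFactors = FALSE)
}

.empty_sites <- function() {
  data.frame(mir_id = character(0), target_id = character(0),
             start = integer(0), end = integer(0),
             site_type = character(0), spans_junction = logical(0),
             stringsAsFactors = FALSE)
}

#' Find miRNA seed-match sites on a linear target
#'
#' Scans the target (a 3'UTR, 5'->3') for the reverse complement of the
#' miRNA seed. Coordinates are 0-based half-open on the target; overlapping
#' sites are all reported, deduplicated by (start, site_type) and sorted by
#' position.
#'
#' @param target target sequence (T/U interchangeable).
#' @param mir mature miRNA sequence.
#' @param rules a [site_rules()] list.
#' @param mir_id,target_id identifiers copied into the output.
#' @return data.frame with columns `mir_id`, `target_id`, `start`, `end`
#'   (0-based half-open), `site_type`, `spans_junction` (always `FALSE`
#'   here).
#' @examples
#' find_sites_linear("GGUUUUUUUGG", paste(rep("A", 22), collapse = ""))
#' @export
find_sites_linear <- function(target, mir, rules = site_rules(),
                              mir_id = "mir", target_id = "target") {
  target <- .canon_rna(target)
  core <- .rna_rc(seed_of(mir, rules$span))
  starts <- .match_starts(core, target)
  cls <- .classify_sites(target, starts, nchar(core), rules$span)
  if (rules$span == "2_7" && !rules$allow_6mer)
    cls <- cls[cls$site_type != "6mer", , drop = FALSE]
  .finish_sites(cls, nchar(target), circular = FALSE,
                mir_id = mir_id, target_id = target_id)
}

#' Find miRNA seed-match sites on a circular target
#'
#' circRNAs are covalently closed, so a seed site may span the back-splice
#' junction, i.e. the joint between the last and first base of the canonical
#' linearisation. Sites are found by scanning the doubled sequence restricted
#' to starts within the first copy; positions are reported modulo the circle
#' length, and `spans_junction` is `TRUE` when the site wraps past the end of
#' the linearisation.
#'
#' @inheritParams find_sites_linear
#' @param circ the back-splice-joined linearisation of the circle.
#' @return as [find_sites_linear()]; `end` may exceed the circle length for
#'   junction-spanning sites (interpret modulo length).
#' @export
find_sites_circular <- function(circ, mir, rules = site_rules(),
                                mir_id = "mir", target_id = "target") {
  circ <- .canon_rna(circ)
  L <- nchar(circ)
  core <- .rna_rc(seed_of(mir, rules$span))
  if (nchar(core) > L) stop("site length exceeds circle length")
  doubled <- paste0(circ, circ)
  starts <- .match_starts(core, doubled)
  starts <- starts[starts <= L]
  cls <- .classify_sites(doubled, starts, nchar(core), rules$span)
  if (rules$span == "2_7" && !rules$allow_6mer)
    cls <- cls[cls$site_type != "6mer", , drop = FALSE]
  .finish_sites(cls, L, circular = TRUE, mir_id = mir_id,
                target_id = target_id)
}

# convert 1-based classified core starts into the exported 0-based site table
.finish_sites <- function(cls, L, circular, mir_id, target_id) {
  if (!nrow(cls)) return(.empty_sites())
  start0 <- cls$start - 1L
  len <- .site_len[cls$site_type]
  if (circular) {
    spans <- start0 + len > L
    start0 <- start0 %% L
  } else {
    keep <- start0 + len <= L  # drop sites whose A1 anchor fell off the end?
    # (cannot happen: classification only assigns the longer type when the
    # anchor base exists; retained as a guard)
    cls <- cls[keep, , drop = FALSE]
    start0 <- start0[keep]
    len <- len[keep]
    spans <- rep(FALSE, length(start0))
  }
  out <- data.frame(mir_id = mir_id, target_id = target_id,
                    start = as.integer(start0),
                    end = as.integer(start0 + len),
                    site_type = cls$site_type, spans_junction = spans,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("start", "site_type")]), , drop = FALSE]
  out[order(out$target_id, out$start, out$site_type), , drop = FALSE]
}

#' Scan a set of miRNAs against a set of targets
#'
#' Convenience wrapper producing one combined site table, sorted by
#' (target_id, start, site_type) for deterministic output.
#'
#' @param targets named character vector of target sequences.
#' @param mirs named character vector of mature miRNA sequences.
#' @param circular scan targets as circles (back-splice-joined)?
#' @param rules a [site_rules()] list.
#' @export
find_sites <- function(targets, mirs, circular = FALSE,
                       rules = site_rules()) {
  stopifnot(length(targets) == 0 || !is.null(names(targets)),
            length(mirs) == 0 || !is.null(names(mirs)))
  fun <- if (circular) find_sites_circular else find_sites_linear
  res <- list()
  for (t in names(targets)) {
    for (m in names(mirs)) {
      res[[length(res) + 1L]] <-
        fun(targets[[t]], mirs[[m]], rules, mir_id = m, target_id = t)
    }
  }
  out <- do.call(rbind, c(list(.empty_sites()), res))
  rownames(out) <- NULL
  out[order(out$target_id, out$start, out$site_type), , drop = FALSE]
}

#' Write a site table as BED-like TSV
#'
#' Columns: target_id, start, end, mir_id, site_type, spans_junction.
#' @param sites a site table from [find_sites()].
#' @param path output path.
#' @export
write_sites <- function(sites, path) {
  df <- sites[, c("target_id", "start", "end", "mir_id", "site_type",
                  "spans_junction")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
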