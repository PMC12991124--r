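# Shared data model: plex layouts, peptide quantification records, protein
# databases, annotation sets, and the plain-text formats they live in.

#' TMT reporter channel label sets
#'
#' Standard reporter-ion channel labels for 10-plex and 16-plex isobaric
#' labeling kits, in mass order. Used as defaults by the simulators; any
#' character labels are accepted throughout the package as long as they are
#' unique within a plex.
#'
#' @format Character vectors of length 10 and 16.
#' @name tmt_channels
NULL

#' @rdname tmt_channels
#' @export
TMT10_CHANNELS <- c(
  "126", "127N", "127C", "128N", "128C",
  "129N", "129C", "130N", "130C", "131"
)

#' @rdname tmt_channels
#' @export
TMT16_CHANNELS <- c(
  "126", "127N", "127C", "128N", "128C", "129N", "129C", "130N",
  "130C", "131N", "131C", "132N", "132C", "133N", "133C", "134N"
)

VALID_TREATMENTS <- c("none", "ATP", "inhibitor")

#' Construct a plex layout
#'
#' A plex layout maps every reporter channel of one or more multiplexed
#' experiments to its biological sample: cell state (condition), replicate
#' index, and lysate treatment arm. The reference condition (the activated
#' state against which all ratios are formed) must be present in every plex
#' so that within-plex ratios are always computable.
#'
#' @param channels Data frame with columns `plex_id`, `channel`, `condition`,
#'   `replicate` and optionally `treatment` (default `"none"`; one of
#'   `"none"`, `"ATP"`, `"inhibitor"`).
#' @param reference_condition Condition used as the ratio denominator
#'   (default `"D2"`, the activated state).
#' @return A tibble of class `plex_layout` with attribute
#'   `reference_condition`.
#' @export
plex_layout <- function(channels, reference_condition = "D2") {
  channels <- as_tibble(channels)
  required <- c("plex_id", "channel", "condition", "replicate")
  missing_cols <- setdiff(required, names(channels))
  if (length(missing_cols) > 0) {
    abort(paste0("layout is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"treatment" %in% names(channels)) channels$treatment <- "none"
  channels$plex_id <- as.character(channels$plex_id)
  channels$channel <- as.character(channels$channel)
  channels$condition <- as.character(channels$condition)
  channels$replicate <- as.integer(channels$replicate)
  channels$treatment <- as.character(channels$treatment)

  if (any(is.na(channels$condition)) || any(!nzchar(channels$condition))) {
    abort("every condition name must be nonempty")
  }
  if (any(is.na(channels$replicate)) || any(channels$replicate < 1L)) {
    abort("replicate indices must be integers >= 1")
  }
  bad_trt <- setdiff(unique(channels$treatment), VALID_TREATMENTS)
  if (length(bad_trt) > 0) {
    abort(paste0("invalid treatment(s): ", paste(bad_trt, collapse = ", "),
                 "; must be one of ", paste(VALID_TREATMENTS, collapse = ", ")))
  }
  dup <- channels %>%
    count(.data$plex_id, .data$channel) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated channel label(s) within a plex: ",
                 paste(unique(dup$channel), collapse = ", ")))
  }
  no_ref <- channels %>%
    group_by(.data$plex_id) %>%
    summarise(has_ref = any(.data$condition == reference_condition),
              .groups = "drop") %>%
    filter(!.data$has_ref)
  if (nrow(no_ref) > 0) {
    abort(paste0("plex(es) lacking the reference condition '",
                 reference_condition, "': ",
                 paste(no_ref$plex_id, collapse = ", ")))
  }
  structure(channels,
            reference_condition = reference_condition,
            class = c("plex_layout", class(channels)))
}

#' Reference condition of a layout
#' @param layout A `plex_layout`.
#' @return The reference condition name.
#' @export
layout_reference <- function(layout) {
  attr(layout, "reference_condition") %||% "D2"
}

#' Read / write a plex layout file
#'
#' The on-disk format is line-oriented plain text: a `reference <condition>`
#' line, then one `plex <id>` header per multiplexed set followed by one line
#' per channel with whitespace-separated fields
#' `channel condition replicate treatment`. Blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @return `read_layout()` returns a `plex_layout`; `write_layout()` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) abort(paste0("layout file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  reference <- NULL
  current_plex <- NULL
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (identical(fields[[1]], "reference")) {
      if (length(fields) != 2L) {
        abort(paste0("malformed reference line at line ", i, ": ", line))
      }
      reference <- fields[[2]]
    } else if (identical(fields[[1]], "plex")) {
      if (length(fields) != 2L) {
        abort(paste0("malformed plex line at line ", i, ": ", line))
      }
      current_plex <- fields[[2]]
    } else {
      if (length(fields) != 4L || is.null(current_plex)) {
        abort(paste0("malformed channel line at line ", i, ": ", line))
      }
      rep_i <- suppressWarnings(as.integer(fields[[3]]))
      if (is.na(rep_i)) {
        abort(paste0("non-integer replicate at line ", i, ": ", line))
      }
      rows[[length(rows) + 1L]] <- tibble(
        plex_id = current_plex, channel = fields[[1]],
        condition = fields[[2]], replicate = rep_i, treatment = fields[[4]]
      )
    }
  }
  if (length(rows) == 0) abort(paste0("no channel lines in layout: ", path))
  plex_layout(bind_rows(rows),
              reference_condition = reference %||% "D2")
}

#' @rdname read_layout
#' @param layout A `plex_layout` to write.
#' @export
write_layout <- function(layout, path) {
  lines <- c(paste("reference", layout_reference(layout)))
  for (px in unique(layout$plex_id)) {
    lines <- c(lines, paste("plex", px))
    sub <- layout[layout$plex_id == px, ]
    lines <- c(lines, paste(sub$channel, sub$condition, sub$replicate,
                            sub$treatment))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a protein sequence database
#'
#' @param sequences Named character vector: accession -> amino-acid sequence.
#'   Sequences are restricted to the 20 standard residues plus `X`.
#' @return Named character vector of class `protein_db`.
#' @export
protein_db <- function(sequences) {
  sequences <- toupper(unlist(sequences))
  acc <- names(sequences)
  if (is.null(acc) || any(!nzchar(acc))) {
    abort("every sequence must carry an accession name")
  }
  if (anyDuplicated(acc)) {
    abort(paste0("duplicate accession(s): ",
                 paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  }
  if (any(!nzchar(sequences))) {
    abort(paste0("empty sequence for accession(s): ",
                 paste(acc[!nzchar(sequences)], collapse = ", ")))
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequences)
  if (any(bad)) {
    abort(paste0("non-standard residues in accession(s): ",
                 paste(acc[bad], collapse = ", ")))
  }
  structure(sequences, class = "protein_db")
}

#' Read / write a protein FASTA database
#'
#' The accession is the header token before the first whitespace.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a `protein_db`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  names(seqs) <- acc
  protein_db(seqs)
}

#' @rdname read_fasta
#' @param db A `protein_db` to write.
#' @export
write_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(unclass(db))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Construct an annotation set
#'
#' Annotation classes (e.g. mitochondrial, nucleotide-binding, typically
#' derived from Gene Ontology terms) are plain sets of protein accessions
#' and may overlap.
#'
#' @param classes Named list: class name -> character vector of accessions.
#' @return Named list of class `annotation_set`.
#' @export
annotation_set <- function(classes) {
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    abort("every annotation class must be named")
  }
  if (anyDuplicated(names(classes))) abort("class names must be unique")
  classes <- lapply(classes, function(x) unique(as.character(x)))
  structure(classes, class = "annotation_set")
}

#' Read / write annotation tables
#'
#' Two-column tab-separated table with header `class`, `accession`.
#'
#' @param path File path.
#' @return `read_annotations()` returns an `annotation_set`.
#' @export
read_annotations <- function(path) {
  tab <- read_tsv(path, col_types = cols(.default = col_character()),
                  progress = FALSE)
  if (!all(c("class", "accession") %in% names(tab))) {
    abort("annotation table needs columns 'class' and 'accession'")
  }
  annotation_set(split(tab$accession, tab$class))
}

#' @rdname read_annotations
#' @param annotations An `annotation_set` to write.
#' @export
write_annotations <- function(annotations, path) {
  tab <- bind_rows(lapply(names(annotations), function(cl) {
    tibble(class = cl, accession = annotations[[cl]])
  }))
  write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

parse_offsets <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(o) {
    o <- o[nzchar(o)]
    as.integer(o)
  })
}

#' Construct peptide quantification records
#'
#' Records are held in long format: one row per (peptide record, channel),
#' `NA` intensity meaning the reporter ion was not observed in that channel.
#' A record is identified by (`plex_id`, `accession`, `sequence`, `offsets`);
#' `offsets` are 1-based positions of probe-modified cysteines *within the
#' peptide* as a semicolon-joined string (empty for unenriched records).
#'
#' @param records Data frame with columns `plex_id`, `accession`, `sequence`,
#'   `offsets`, `channel`, `intensity`.
#' @param enriched Logical: do these records come from the cysteine-probe
#'   enriched experiment (every record must then carry >= 1 modified offset)?
#' @return Tibble of class `peptide_quant` with attribute `enriched`.
#' @export
peptide_quant <- function(records, enriched = FALSE) {
  records <- as_tibble(records)
  required <- c("plex_id", "accession", "sequence", "offsets", "channel",
                "intensity")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records$offsets <- ifelse(is.na(records$offsets), "", records$offsets)
  records$sequence <- toupper(as.character(records$sequence))
  if (any(records$intensity < 0, na.rm = TRUE)) {
    abort("negative intensity encountered; intensities must be nonnegative")
  }

  keys <- records %>%
    distinct(.data$plex_id, .data$accession, .data$sequence, .data$offsets)
  offs <- parse_offsets(keys$offsets)
  if (enriched && any(lengths(offs) == 0L)) {
    bad <- keys$sequence[lengths(offs) == 0L]
    abort(paste0("enriched record(s) without modified offsets: ",
                 paste(unique(bad), collapse = ", ")))
  }
  for (i in seq_len(nrow(keys))) {
    o <- offs[[i]]
    if (length(o) == 0L) next
    sq <- keys$sequence[[i]]
    if (any(is.na(o)) || any(o < 1L) || any(o > nchar(sq))) {
      abort(paste0("offset out of range for peptide ", sq))
    }
    res <- substring(sq, o, o)
    if (any(res != "C")) {
      abort(paste0("modified offset does not point at a cysteine in peptide ",
                   sq))
    }
  }
  n_obs <- records %>%
    group_by(.data$plex_id, .data$accession, .data$sequence, .data$offsets) %>%
    summarise(n = sum(!is.na(.data$intensity)), .groups = "drop")
  if (any(n_obs$n == 0L)) {
    abort("record(s) with no observed intensity in any channel")
  }
  structure(records, enriched = enriched,
            class = unique(c("peptide_quant", class(records))))
}

#' Read a peptide quantification table
#'
#' Tab-separated table with header columns `accession`, `sequence`,
#' `offsets` (semicolon-joined 1-based peptide positions of modified
#' cysteines; empty for unenriched data) followed by one intensity column
#' per reporter channel of the plex. Empty cells are missing observations
#' and are never coerced to zero; a literal `0` is an observed value.
#'
#' @param path File path.
#' @param layout A `plex_layout` naming the channels expected in the header.
#' @param enriched Logical, as in [peptide_quant()].
#' @param plex_id Which plex of `layout` this table belongs to; may be
#'   omitted when the layout holds a single plex.
#' @return A `peptide_quant` tibble in long format.
#' @export
read_quant_table <- function(path, layout, enriched = FALSE, plex_id = NULL) {
  plexes <- unique(layout$plex_id)
  if (is.null(plex_id)) {
    if (length(plexes) != 1L) {
      abort("layout holds multiple plexes; supply plex_id")
    }
    plex_id <- plexes
  }
  if (!plex_id %in% plexes) {
    abort(paste0("plex '", plex_id, "' not present in layout"))
  }
  channels <- layout$channel[layout$plex_id == plex_id]
  tab <- read_tsv(path, col_types = cols(.default = col_character()),
                  na = "", progress = FALSE)
  for (col in c("accession", "sequence", "offsets")) {
    if (!col %in% names(tab)) {
      abort(paste0("quant table lacks required column '", col, "'"))
    }
  }
  missing_ch <- setdiff(channels, names(tab))
  if (length(missing_ch) > 0) {
    abort(paste0("quant table lacks channel column(s) named by layout: ",
                 paste(missing_ch, collapse = ", ")))
  }
  tab <- tab[, c("accession", "sequence", "offsets", channels)]
  long <- pivot_longer(tab, cols = all_of(channels), names_to = "channel",
                       values_to = "intensity")
  long$intensity <- suppressWarnings(as.numeric(long$intensity))
  long$offsets <- ifelse(is.na(long$offsets), "", long$offsets)
  long$plex_id <- plex_id
  long <- long[, c("plex_id", "accession", "sequence", "offsets", "channel",
                   "intensity")]
  peptide_quant(long, enriched = enriched)
}

#' Write a peptide quantification table
#'
#' Inverse of [read_quant_table()]: one row per record, channel columns in
#' layout order, missing intensities as empty cells.
#'
#' @inheritParams read_quant_table
#' @param records A `peptide_quant` tibble (single plex).
#' @export
write_quant_table <- function(records, path, layout = NULL) {
  plexes <- unique(records$plex_id)
  if (length(plexes) != 1L) {
    abort("write_quant_table() expects records from a single plex")
  }
  if (!is.null(layout)) {
    channels <- layout$channel[layout$plex_id == plexes]
  } else {
    channels <- unique(records$channel)
  }
  wide <- pivot_wider(records,
                      id_cols = c("accession", "sequence", "offsets"),
                      names_from = "channel", values_from = "intensity")
  wide <- wide[, c("accession", "sequence", "offsets", channels)]
  write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write / read a generic results table
#'
#' Tab-separated with header, missing values as empty cells, deterministic
#' column order (as given). These round-trip all call and quant tables the
#' pipeline produces.
#'
#' @param x Data frame.
#' @param path File path.
#' @export
write_table <- function(x, path) {
  write_tsv(as_tibble(x), path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  read_tsv(path, na = "", progress = FALSE, show_col_types = FALSE)
}
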