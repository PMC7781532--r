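#' @keywords internal
read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", strip.white = TRUE)
}

write_delim_auto <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = TRUE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
}

find_sheet <- function(dir, sheet) {
  cand <- file.path(dir, paste0(sheet, c(".csv", ".tsv")))
  hit <- cand[file.exists(cand)]
  if (!length(hit)) {
    stop(sprintf("no '%s' sheet (%s.csv or %s.tsv) found in %s",
                 sheet, sheet, sheet, dir), call. = FALSE)
  }
  hit[1]
}

keep_schema_cols <- function(df, schema, sheet) {
  extra <- setdiff(names(df), schema)
  if (length(extra)) {
    message(sprintf("ignoring non-schema column(s) in %s sheet: %s",
                    sheet, paste(extra, collapse = ", ")))
  }
  df[, intersect(schema, names(df)), drop = FALSE]
}

#' Read a network model from species/reactions tables
#'
#' Reads the Netflux-style two-sheet layout: a `species` table (columns `id`,
#' optional `name`, `role`, `Ymax`, `Y0`, `tau`) and a `reactions` table
#' (columns `id`, `rule`, optional `W_R`, `n`, `EC50`). `path` may be a
#' directory containing `species.csv`/`reactions.csv` (or `.tsv`), or the two
#' files may be named explicitly. Empty parameter cells mean "use default".
#' Columns outside the schema are ignored with a message.
#'
#' @param path directory holding the two sheets (ignored when both `species`
#'   and `reactions` are given).
#' @param species,reactions optional explicit file paths.
#' @return a [network_model()].
#' @export
read_network <- function(path = NULL, species = NULL, reactions = NULL) {
  if (is.null(species) || is.null(reactions)) {
    if (is.null(path) || !dir.exists(path)) {
      stop("give a directory `path` or both `species` and `reactions` files",
           call. = FALSE)
    }
    species <- find_sheet(path, "species")
    reactions <- find_sheet(path, "reactions")
  }
  sp <- read_delim_auto(species)
  rx <- read_delim_auto(reactions)
  if (!"id" %in% names(sp)) stop("species sheet: missing required column 'id'", call. = FALSE)
  if (!all(c("id", "rule") %in% names(rx))) {
    stop("reactions sheet: missing required column(s) 'id'/'rule'", call. = FALSE)
  }
  sp <- keep_schema_cols(sp, c("id", "name", "role", "Ymax", "Y0", "tau"), "species")
  rx <- keep_schema_cols(rx, c("id", "rule", "W_R", "n", "EC50"), "reactions")
  network_model(sp, rx)
}

#' Write a network model to species/reactions tables
#'
#' Inverse of [read_network()]: writes `species.csv` and `reactions.csv`
#' under `path` (created if absent). `read_network(write_network(m))` is the
#' identity on ids, rule strings and per-element parameters.
#'
#' @param model a [network_model()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_network <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_delim_auto(model$nodes, file.path(path, "species.csv"))
  rx <- model$reactions[, c("id", "rule", "W_R", "n", "EC50")]
  write_delim_auto(rx, file.path(path, "reactions.csv"))
  invisible(path)
}

# ---- experiment records -----------------------------------------------------

.data_classes <- c("InputOutput", "InputIntermediate",
                   "IntermediateInhibition", "IntermediateOverexpression")
.directions <- c("increase", "decrease", "nochange")
.fold_categories <- c("HH", "MH", "LH", "LL", "ML", "HL")

normalize_data_class <- function(x) {
  key <- tolower(gsub("[^a-z]", "", tolower(x)))
  map <- c(inputoutput = "InputOutput",
           inputintermediate = "InputIntermediate",
           intermediateinhibition = "IntermediateInhibition",
           intermediateoverexpression = "IntermediateOverexpression")
  out <- unname(map[key])
  if (any(is.na(out))) {
    stop("unknown data class label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected one of ", paste(.data_classes, collapse = ", "), ")",
         call. = FALSE)
  }
  out
}

normalize_direction <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  map <- c(increase = "increase", decrease = "decrease",
           nochange = "nochange", nc = "nochange")
  out <- unname(map[key])
  if (any(is.na(out))) {
    bad <- unique(x[is.na(out)])
    hint <- c(up = "increase", down = "decrease", inc = "increase",
              dec = "decrease")[gsub("[^a-z]", "", tolower(bad))]
    extra <- if (any(!is.na(hint))) {
      paste0("; did you mean ", paste(stats::na.omit(hint), collapse = ", "), "?")
    } else ""
    stop("unknown direction token(s): ", paste(bad, collapse = ", "), extra,
         call. = FALSE)
  }
  out
}

normalize_observed <- function(x) {
  up <- toupper(trimws(x))
  is_cat <- up %in% .fold_categories
  out <- character(length(x))
  out[is_cat] <- up[is_cat]
  if (any(!is_cat)) out[!is_cat] <- normalize_direction(x[!is_cat])
  list(observed = out,
       type = ifelse(is_cat, "semiquant", "qualitative"))
}

#' Parse a perturbation token string
#'
#' Tokens are semicolon-separated: `stim:<input node>`, `inhib:<node>`,
#' `oex:<node>`, `del:<reaction>`, `w:<reaction>=<value>`. A `stim` token may
#' carry an explicit input weight as `stim:<node>=<value>`.
#'
#' @param x single token string.
#' @return list of perturbations, each `list(kind, target, value)`.
#' @export
parse_perturbations <- function(x) {
  toks <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("record with no perturbation", call. = FALSE)
  kinds <- c(stim = "stimulus", inhib = "knockdown", oex = "overexpression",
             del = "reaction_deletion", w = "reaction_weight")
  lapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^([a-z]+):([^=]+)(=(.*))?$", tk))[[1]]
    if (length(m) == 0L || !m[2] %in% names(kinds)) {
      stop(sprintf("unknown perturbation token '%s' (expected %s)",
                   tk, paste0(names(kinds), ":", collapse = "..., ")),
           call. = FALSE)
    }
    value <- if (nzchar(m[5])) as.numeric(m[5]) else NA_real_
    perturbation(kinds[[m[2]]], trimws(m[3]), value)
  })
}

format_perturbations <- function(perts) {
  abbr <- c(stimulus = "stim", knockdown = "inhib", overexpression = "oex",
            reaction_deletion = "del", reaction_weight = "w")
  paste(vapply(perts, function(p) {
    tok <- paste0(abbr[[p$kind]], ":", p$target)
    if (!is.na(p$value)) tok <- paste0(tok, "=", format(p$value))
    tok
  }, character(1)), collapse = ";")
}

#' Read an experiment table
#'
#' One row per curated observation, columns `record_id`, `context`,
#' `data_class`, `perturbations` (token dialect of [parse_perturbations()]),
#' `measured_node`, `observed` and optional `source`. `observed` is either a
#' qualitative direction (`increase`/`decrease`/`nochange`) or one of the six
#' semi-quantitative fold categories `HH MH LH LL ML HL`.
#'
#' @param path CSV/TSV file.
#' @return data.frame of class `experiment_records` with a `perturbations`
#'   list column and a `type` column (`qualitative`/`semiquant`).
#' @export
read_experiments <- function(path) {
  df <- read_delim_auto(path)
  req <- c("record_id", "context", "data_class", "perturbations",
           "measured_node", "observed")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("experiment table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  experiment_records(df)
}

#' Assemble experiment records from a data.frame
#'
#' Normalizes vocabulary (data classes, directions, fold categories) and
#' parses the perturbation tokens; see [read_experiments()] for the schema.
#'
#' @param df data.frame with the experiment-table columns; `perturbations`
#'   may already be a list column.
#' @return `experiment_records` data.frame.
#' @export
experiment_records <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) > 0L)
  obs <- normalize_observed(as.character(df$observed))
  perts <- if (is.list(df$perturbations)) {
    df$perturbations
  } else {
    lapply(as.character(df$perturbations), parse_perturbations)
  }
  out <- data.frame(
    record_id = as.character(df$record_id),
    context = trimws(as.character(df$context)),
    data_class = normalize_data_class(as.character(df$data_class)),
    measured_node = trimws(as.character(df$measured_node)),
    observed = obs$observed,
    type = obs$type,
    source = if (is.null(df$source)) "" else as.character(df$source),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$record_id)) {
    stop("duplicate record_id values", call. = FALSE)
  }
  out$perturbations <- I(perts)
  class(out) <- c("experiment_records", "data.frame")
  out
}

#' Write an experiment table
#'
#' Inverse of [read_experiments()].
#'
#' @param records `experiment_records`.
#' @param path output CSV/TSV path.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(records, path) {
  df <- as.data.frame(records)
  df$perturbations <- vapply(records$perturbations, format_perturbations,
                             character(1))
  write_delim_auto(df[, c("record_id", "context", "data_class", "perturbations",
                          "measured_node", "observed", "source")], path)
  invisible(path)
}

#' Check that records reference only elements of a model
#'
#' @param records `experiment_records`.
#' @param model a [network_model()].
#' @return `records`, invisibly; errors naming the offending record otherwise.
#' @export
check_records <- function(records, model) {
  nodes <- model$nodes$id
  rxns <- model$reactions$id
  for (i in seq_len(nrow(records))) {
    if (!records$measured_node[i] %in% nodes) {
      stop(sprintf("record '%s': measured node '%s' not in model",
                   records$record_id[i], records$measured_node[i]), call. = FALSE)
    }
    for (p in records$perturbations[[i]]) {
      pool <- if (p$kind %in% c("reaction_deletion", "reaction_weight")) rxns else nodes
      if (!p$target %in% pool) {
        stop(sprintf("record '%s': perturbation target '%s' not in model",
                     records$record_id[i], p$target), call. = FALSE)
      }
    }
  }
  invisible(records)
}
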