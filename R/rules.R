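#' Parse a Boolean reaction rule
#'
#' Rules follow the Netflux spreadsheet dialect: `[!]X ( & [!]Y )* => Z` for
#' signaling reactions (reactants combined by AND, `!` marking an inhibiting
#' reactant) and `=> Z` for receptor input (source) reactions with no
#' reactants.
#'
#' @param rule single rule string, e.g. `"!A & B => C"` or `"=> ISO"`.
#' @return list with fields `reactants` (data.frame `node`, `sign` in
#'   `{"activating","inhibiting"}`, in rule order), `target` (node id) and
#'   `is_input` (logical).
#' @examples
#' parse_rule("!A & B => C")
#' parse_rule("=> ISO")
#' @export
parse_rule <- function(rule) {
  if (!is.character(rule) || length(rule) != 1L || !nzchar(trimws(rule))) {
    stop("rule must be a single non-empty string", call. = FALSE)
  }
  raw <- rule
  if (grepl("=>.*=>", rule)) {
    stop(sprintf("malformed rule '%s': expected one '=>'", raw), call. = FALSE)
  }
  parts <- strsplit(rule, "=>", fixed = TRUE)[[1]]
  if (length(parts) < 2L || !grepl("=>", rule, fixed = TRUE)) {
    stop(sprintf("malformed rule '%s': empty or missing target", raw), call. = FALSE)
  }
  lhs <- trimws(parts[1])
  target <- trimws(parts[2])
  if (!nzchar(target) || grepl("[!&[:space:]]", target)) {
    stop(sprintf("malformed rule '%s': empty or invalid target", raw), call. = FALSE)
  }
  if (!nzchar(lhs)) {
    return(list(
      reactants = data.frame(node = character(), sign = character(),
                             stringsAsFactors = FALSE),
      target = target, is_input = TRUE
    ))
  }
  toks <- trimws(strsplit(lhs, "&", fixed = TRUE)[[1]])
  if (any(!nzchar(toks))) {
    stop(sprintf("malformed rule '%s': empty reactant token", raw), call. = FALSE)
  }
  inhib <- startsWith(toks, "!")
  ids <- trimws(sub("^!", "", toks))
  if (any(!nzchar(ids)) || any(grepl("[!&[:space:]]", ids))) {
    stop(sprintf("malformed rule '%s': invalid reactant id", raw), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("malformed rule '%s': duplicate reactant id '%s'",
                 raw, ids[duplicated(ids)][1]), call. = FALSE)
  }
  list(
    reactants = data.frame(
      node = ids,
      sign = ifelse(inhib, "inhibiting", "activating"),
      stringsAsFactors = FALSE
    ),
    target = target, is_input = FALSE
  )
}

#' Format a parsed rule back to its string form
#'
#' Inverse of [parse_rule()] up to whitespace normalization.
#'
#' @param reactants data.frame with columns `node`, `sign`.
#' @param target target node id.
#' @return rule string.
#' @export
format_rule <- function(reactants, target) {
  if (nrow(reactants) == 0L) return(paste("=>", target))
  lhs <- paste0(ifelse(reactants$sign == "inhibiting", "!", ""), reactants$node)
  paste(paste(lhs, collapse = " & "), "=>", target)
}
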