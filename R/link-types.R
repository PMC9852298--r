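#' Declare the set of link types of a typed bipartite network
#'
#' A link-type set names the qualitative labels that agent-event connections
#' can carry (for example support/oppose/abstain votes, or buy/sell/day-trade
#' states), and optionally designates some types as *neutral* and some
#' unordered pairs as mutually *opposing*. Opposing pairs are what make
#' negative-link validation possible: two agents oppose each other at an event
#' when one uses `a_plus` and the other `a_minus` of a declared opposing pair.
#'
#' @param types Character vector of distinct link-type identifiers.
#' @param neutral Optional character vector, subset of `types`, of types
#'   considered neutral (they enter positive-overlap counts but never
#'   opposing-overlap counts).
#' @param opposing Optional list of length-2 character vectors, each an
#'   unordered pair of mutually opposing types. A type may not be both
#'   neutral and a member of an opposing pair.
#'
#' @return An object of class `link_type_set`.
#' @examples
#' link_type_set(c("S", "O", "A"), neutral = "A", opposing = list(c("S", "O")))
#' @export
link_type_set <- function(types, neutral = NULL, opposing = NULL) {
  types <- as.character(types)
  if (length(types) == 0) stop("`types` must be non-empty")
  if (anyDuplicated(types)) stop("`types` must not contain duplicates")
  neutral <- as.character(neutral %||% character())
  if (!all(neutral %in% types)) {
    stop("neutral types not registered: ",
         paste(setdiff(neutral, types), collapse = ", "))
  }
  opposing <- lapply(opposing %||% list(), function(p) {
    p <- as.character(p)
    if (length(p) != 2 || p[1] == p[2]) {
      stop("each opposing pair must be two distinct types")
    }
    if (!all(p %in% types)) {
      stop("opposing pair references unknown type: ", paste(p, collapse = ", "))
    }
    sort_ids(p)
  })
  in_opposing <- unique(unlist(opposing))
  clash <- intersect(neutral, in_opposing)
  if (length(clash) > 0) {
    stop("types cannot be both neutral and opposing: ",
         paste(clash, collapse = ", "))
  }
  structure(
    list(types = types, neutral = neutral, opposing = opposing),
    class = "link_type_set"
  )
}

#' @export
print.link_type_set <- function(x, ...) {
  cat("<link_type_set>", length(x$types), "types:",
      paste(x$types, collapse = ", "), "\n")
  if (length(x$neutral)) cat("  neutral:", paste(x$neutral, collapse = ", "), "\n")
  if (length(x$opposing)) {
    cat("  opposing:",
        paste(vapply(x$opposing, paste, "", collapse = "/"), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read or write a link-type declaration as JSON
#'
#' The JSON config holds the link-type declaration (`types`, `neutral`,
#' `opposing`) and, optionally, the full ordered `agents` and `events`
#' universes of a network, so that events no agent attended survive a
#' round trip through the tabular incidence format.
#'
#' @param path Path of the JSON file.
#' @return `read_link_config()` returns a list with elements `link_types`
#'   (a [link_type_set]), `agents` and `events` (character vectors or `NULL`).
#' @seealso [read_incidence()], [write_incidence()]
#' @export
read_link_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  opposing <- cfg$opposing
  if (is.matrix(opposing)) opposing <- asplit(opposing, 1)
  if (is.character(opposing)) opposing <- list(opposing)
  list(
    link_types = link_type_set(cfg$types, neutral = cfg$neutral,
                               opposing = opposing),
    agents = cfg$agents,
    events = cfg$events
  )
}

#' @param net A [typed_bipartite()] network whose declaration is written.
#' @rdname read_link_config
#' @export
write_link_config <- function(net, path) {
  stopifnot(inherits(net, "typed_bipartite"))
  lt <- net$types
  cfg <- list(types = lt$types, neutral = lt$neutral, opposing = lt$opposing,
              agents = net$agents, events = net$events)
  jsonlite::write_json(cfg, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
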