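## Species x trait tables for three-state categorical characters with
## missing data, including the bundled blowfly (Calliphoridae) dataset.

#' Define a three-state categorical trait
#'
#' @param name Trait identifier (single string).
#' @param states Character vector of exactly three unique state labels. Their
#'   order fixes the state indices 0, 1, 2 used in rate labels `q[i->j]`.
#' @param missing_token Label marking unavailable data (default `"NA"`);
#'   must not collide with a state label.
#' @return An object of class `trait_definition`.
#' @examples
#' trait_definition("substrate", c("necrotic", "fresh", "both"))
#' @export
trait_definition <- function(name, states, missing_token = "NA") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(states) != 3L || anyDuplicated(states) || !all(nzchar(states)))
    stop("'states' must be 3 unique non-empty labels", call. = FALSE)
  if (missing_token %in% states)
    stop("missing_token collides with a state label", call. = FALSE)
  structure(list(name = name, states = as.character(states),
                 missing_token = missing_token),
            class = "trait_definition")
}

#' Trait definitions for the bundled blowfly dataset
#'
#' Three myiasis-associated characters: trophic specialization
#' (obligatory parasite / saprophagous / facultative parasite), larval food
#' substrate (necrotic / fresh / both), and larval developmental temperature
#' (constant / variable / both). "Both" is a genuine third state, not
#' ambiguity; only the missing token denotes ambiguity.
#'
#' @return Named list of three [trait_definition()] objects.
#' @export
blowfly_trait_definitions <- function() {
  list(
    trophic = trait_definition(
      "trophic", c("obligatory parasite", "saprophagous", "facultative parasite")),
    substrate = trait_definition(
      "substrate", c("necrotic", "fresh", "both")),
    temperature = trait_definition(
      "temperature", c("constant", "variable", "both"))
  )
}

## canonical species key: trim, collapse runs of whitespace/underscores
canonical_species <- function(x) {
  x <- gsub("[ _\t]+", "_", trimws(as.character(x)))
  x
}

#' Parse a species-by-trait table
#'
#' Reads a delimited text file with a `species` column and one column per
#' trait. Cells must be a defined state label or the trait's missing token;
#' anything else is an error naming the offending row and column. State
#' matching is case-insensitive; species names are matched exactly after
#' trimming surrounding and collapsing internal whitespace/underscores.
#'
#' @param path Path to a CSV or TSV file (separator sniffed from the header).
#' @param defs Named list of [trait_definition()]s; default
#'   [blowfly_trait_definitions()].
#' @param ingroup_flags Optional logical vector (recycled or named by
#'   species) marking ingroup membership; defaults to all `TRUE`.
#' @return A `trait_matrix`: data frame with a `species` column and one
#'   factor-free character column per trait, plus attributes `defs` and
#'   `ingroup`.
#' @export
parse_trait_table <- function(path, defs = blowfly_trait_definitions(),
                              ingroup_flags = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           comment.char = "", strip.white = TRUE)
  if (!"species" %in% names(raw))
    stop("trait table must have a 'species' column", call. = FALSE)
  missing_traits <- setdiff(names(defs), names(raw))
  if (length(missing_traits))
    stop("trait table lacks column(s): ", paste(missing_traits, collapse = ", "),
         call. = FALSE)
  species <- canonical_species(raw$species)
  dup <- species[duplicated(species)]
  if (length(dup))
    stop("duplicate species: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  for (tr in names(defs)) {
    def <- defs[[tr]]
    cell <- trimws(raw[[tr]])
    mapped <- character(length(cell))
    lows <- tolower(def$states)
    for (i in seq_along(cell)) {
      if (tolower(cell[i]) == tolower(def$missing_token)) {
        mapped[i] <- def$missing_token
      } else {
        hit <- match(tolower(cell[i]), lows)
        if (is.na(hit))
          stop(sprintf("unrecognized state '%s' (row %d, column '%s')",
                       cell[i], i, tr), call. = FALSE)
        mapped[i] <- def$states[hit]
      }
    }
    out[[tr]] <- mapped
  }
  if (is.null(ingroup_flags)) ingroup_flags <- rep(TRUE, nrow(out))
  attr(out, "defs") <- defs
  attr(out, "ingroup") <- as.logical(ingroup_flags)
  class(out) <- c("trait_matrix", "data.frame")
  out
}

#' Write a trait matrix back to CSV
#'
#' Inverse of [parse_trait_table()]: writing then re-parsing reproduces the
#' trait matrix exactly.
#'
#' @param matrix A `trait_matrix`.
#' @param path Output file path.
#' @export
write_trait_table <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled blowfly trait table (61 Calliphoridae species)
#'
#' @return The packaged species-by-trait matrix of trophic specialization,
#'   larval food substrate, and developmental temperature.
#' @export
blowfly_traits <- function() {
  parse_trait_table(system.file("extdata", "table1_traits.csv",
                                package = "rjmk", mustWork = TRUE))
}

#' Bundled species/accession metadata (61 Calliphoridae + 3 Sarcophagidae)
#'
#' GenBank accession identifiers per marker are metadata only; nothing is
#' ever fetched.
#'
#' @return Data frame with columns family, species, and one column per
#'   marker (empty string when no accession exists).
#' @export
blowfly_accessions <- function() {
  utils::read.table(system.file("extdata", "table2_accessions.csv",
                                package = "rjmk", mustWork = TRUE),
                    sep = ",", header = TRUE, colClasses = "character",
                    na.strings = NULL)
}

#' Summarize one trait of a trait matrix
#'
#' @param matrix A `trait_matrix`.
#' @param trait Trait identifier (must be defined in the matrix).
#' @return A `trait_summary` list: `counts` (named per-state tally over
#'   non-missing species), `n_observed`, `n_missing`.
#' @export
summarize_trait <- function(matrix, trait) {
  defs <- attr(matrix, "defs")
  if (!trait %in% names(defs)) stop("unknown trait: ", trait, call. = FALSE)
  def <- defs[[trait]]
  x <- matrix[[trait]]
  obs <- x != def$missing_token
  counts <- vapply(def$states, function(s) sum(x[obs] == s), integer(1))
  structure(list(trait = trait, counts = counts,
                 n_observed = sum(obs), n_missing = sum(!obs)),
            class = "trait_summary")
}

#' @export
print.trait_summary <- function(x, ...) {
  cat(sprintf("Trait '%s': %d observed, %d missing\n",
              x$trait, x$n_observed, x$n_missing))
  print(x$counts)
  invisible(x)
}

#' Tip likelihood vector for one observation
#'
#' Observed states map to indicator vectors; the missing token maps to the
#' all-ones vector (full ambiguity across the three states).
#'
#' @param obs A state label or the missing token.
#' @param def A [trait_definition()].
#' @return Numeric vector of length 3.
#' @export
tip_likelihood_vector <- function(obs, def) {
  obs <- trimws(obs)
  if (tolower(obs) == tolower(def$missing_token)) return(rep(1, 3))
  hit <- match(tolower(obs), tolower(def$states))
  if (is.na(hit)) stop("undefined state label: ", obs, call. = FALSE)
  v <- numeric(3)
  v[hit] <- 1
  v
}

#' Tip likelihood matrix for a whole trait column
#'
#' @param matrix A `trait_matrix`.
#' @param trait Trait identifier.
#' @return Numeric matrix (species x 3) with species row names, in the
#'   matrix's species order.
#' @export
tip_likelihood_matrix <- function(matrix, trait) {
  defs <- attr(matrix, "defs")
  if (!trait %in% names(defs)) stop("unknown trait: ", trait, call. = FALSE)
  def <- defs[[trait]]
  m <- t(vapply(matrix[[trait]], tip_likelihood_vector, numeric(3), def = def))
  rownames(m) <- matrix$species
  colnames(m) <- def$states
  m
}
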