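# Snapshot and matrix input/output: JSON community snapshots, CSV matrix
# and edge-list exports of the interaction-strength matrix.

#' Write / read a community snapshot (JSON)
#'
#' The snapshot stores the parameter set, both guild states, and the alien
#' marker, and round-trips through [read_community_json()].
#'
#' @param community a [community()] object.
#' @param file path to a JSON file.
#' @return `write_community_json` returns `file` invisibly;
#'   `read_community_json` returns the community.
#' @export
write_community_json <- function(community, file) {
  comm <- as_community(community)
  obj <- list(params = unclass(comm$params),
              animals = comm$animals, plants = comm$plants,
              alien_index = comm$alien_index,
              alien_sigma_m = comm$alien_sigma_m)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(file)
}

#' @rdname write_community_json
#' @export
read_community_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  p <- do.call(model_params, obj$params[setdiff(names(obj$params), NULL)])
  ai <- if (is.null(obj$alien_index) || is.na(obj$alien_index)) NA_integer_
        else as.integer(obj$alien_index)
  asm <- if (is.null(obj$alien_sigma_m) || is.na(obj$alien_sigma_m)) NA_real_
         else obj$alien_sigma_m
  community(guild_state(obj$animals$traits, obj$animals$densities, obj$animals$ids),
            guild_state(obj$plants$traits, obj$plants$densities, obj$plants$ids),
            p, alien_index = ai, alien_sigma_m = asm)
}

#' Export an interaction matrix as CSV
#'
#' `format = "matrix"` writes the full matrix with `A<i>` row and `P<j>`
#' column headers; `format = "edges"` writes a sparse edge list
#' (animal, plant, q) of the non-zero interactions.
#'
#' @param Q an interaction matrix (see [interaction_strength_matrix()]).
#' @param file output path.
#' @param format `"matrix"` or `"edges"`.
#' @return `file`, invisibly.
#' @export
write_interaction_matrix <- function(Q, file, format = c("matrix", "edges")) {
  format <- match.arg(format)
  Q <- unclass(as.matrix(Q))
  if (is.null(rownames(Q))) rownames(Q) <- paste0("A", seq_len(nrow(Q)))
  if (is.null(colnames(Q))) colnames(Q) <- paste0("P", seq_len(ncol(Q)))
  if (format == "matrix") {
    write.csv(Q, file)
  } else {
    idx <- which(Q > 0, arr.ind = TRUE)
    edges <- data.frame(animal = rownames(Q)[idx[, 1]],
                        plant = colnames(Q)[idx[, 2]],
                        q = Q[idx])
    write.csv(edges[order(edges$animal, edges$plant), ], file,
              row.names = FALSE)
  }
  invisible(file)
}

#' Read an interaction matrix from CSV
#'
#' Accepts either the full-matrix layout or the edge-list layout written by
#' [write_interaction_matrix()] (autodetected by the header).
#'
#' @param file CSV path.
#' @return a numeric matrix with `A<i>` / `P<j>` dimnames.
#' @export
read_interaction_matrix <- function(file) {
  head1 <- names(read.csv(file, nrows = 1, check.names = FALSE))
  if (all(c("animal", "plant", "q") %in% head1)) {
    edges <- read.csv(file)
    an <- sort(unique(edges$animal)); pl <- sort(unique(edges$plant))
    Q <- matrix(0, length(an), length(pl), dimnames = list(an, pl))
    Q[cbind(match(edges$animal, an), match(edges$plant, pl))] <- edges$q
  } else {
    df <- read.csv(file, row.names = 1, check.names = FALSE)
    Q <- as.matrix(df)
  }
  Q
}
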