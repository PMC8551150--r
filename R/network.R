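ALL_EDGES <- c("RS->RS", "RS->FS", "FS->RS", "FS->FS",
               "RS->LTS", "FS->LTS", "LTS->RS", "LTS->FS")
RS_FS_EDGES <- c("RS->RS", "RS->FS", "FS->RS", "FS->FS")

#' Type-pair connection probabilities
#'
#' Directed connection probabilities between cell-type populations
#' (rows = postsynaptic, columns = presynaptic): RS receives from RS/FS/LTS
#' with 5/30/40%, FS with 10/30/20%, LTS with 10/20/0%. LTS cells are never
#' connected to each other.
#'
#' @return 3x3 numeric matrix with dimnames `post` x `pre`.
#' @export
connection_probs <- function() {
  m <- matrix(c(0.05, 0.30, 0.40,
                0.10, 0.30, 0.20,
                0.10, 0.20, 0.00),
              nrow = 3, byrow = TRUE,
              dimnames = list(post = c("RS", "FS", "LTS"),
                              pre = c("RS", "FS", "LTS")))
  m
}

edge_prob <- function(edge) {
  parts <- strsplit(edge, "->", fixed = TRUE)[[1]]
  p <- connection_probs()
  if (!parts[1] %in% colnames(p) || !parts[2] %in% rownames(p))
    stop_config("edge '%s' not covered by the probability table", edge)
  p[parts[2], parts[1]]
}

#' Sample one random connectivity block
#'
#' Every candidate pre -> post pair is connected independently with
#' probability `p`; self-connections are excluded when the block connects a
#' population to itself.
#'
#' @param n_pre,n_post population sizes.
#' @param p connection probability in `[0, 1]`.
#' @param same_population exclude the diagonal (no autapses)?
#' @return logical `n_pre` x `n_post` adjacency matrix (rows = presynaptic).
#' @export
build_connection_block <- function(n_pre, n_post, p, same_population = FALSE) {
  if (p < 0 || p > 1) stop_config("connection probability must be in [0, 1]")
  m <- matrix(runif(n_pre * n_post) < p, nrow = n_pre)
  if (same_population && n_pre == n_post && n_pre > 0) diag(m) <- FALSE
  m
}

#' Sample synaptic weights for one presynaptic type
#'
#' Weights are i.i.d. normal draws with the type's mean and SD (1 +- 0.5 for
#' RS, -2 +- 1 for FS and LTS), one draw per synapse. By default draws are
#' not truncated, so a small fraction of "inhibitory" weights may come out
#' positive; `clip_sign = TRUE` clips weights to the sign of the mean.
#'
#' @param spec the presynaptic [cell_type_spec()].
#' @param n number of synapses.
#' @param clip_sign clip draws to the distribution mean's sign?
#' @return numeric vector of length `n`.
#' @export
sample_weights <- function(spec, n, clip_sign = FALSE) {
  if (n < 0) stop_config("n must be >= 0")
  w <- rnorm(n, spec$weight_mean, spec$weight_sd)
  if (clip_sign) {
    if (spec$weight_mean > 0) w <- pmax(w, 0) else w <- pmin(w, 0)
  }
  w
}

#' Motif specification
#'
#' A circuit motif is a set of directed type-pair connections plus the input
#' regime of the LTS population (`"none"` for the RS-FS motif,
#' `"external_only"`, `"local_only"` or `"both"`). Motif I is the two-cell
#' RS-FS circuit, motif II the two-cell RS-LTS circuit; the 18 three-cell
#' motifs keep all four RS/FS connections and differ in LTS wiring.
#'
#' @param motif_id roman-numeral identifier ("I".."XX" or a custom label).
#' @param edges character vector of directed edges, e.g. `"LTS->FS"`.
#' @param lts_input_regime LTS input regime (see above).
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(motif_id, edges,
                       lts_input_regime = c("none", "external_only",
                                            "local_only", "both")) {
  lts_input_regime <- match.arg(lts_input_regime)
  bad <- setdiff(edges, ALL_EDGES)
  if (length(bad))
    stop_config("unknown edge(s): %s", paste(bad, collapse = ", "))
  if ("LTS->LTS" %in% edges)
    stop_config("LTS->LTS connections do not exist")
  has_lts <- lts_input_regime != "none" || any(grepl("LTS", edges))
  local_exc <- "RS->LTS" %in% edges
  if (has_lts && lts_input_regime %in% c("local_only", "both") && !local_exc)
    stop_config("regime '%s' requires the RS->LTS edge", lts_input_regime)
  structure(list(motif_id = motif_id, edges = edges,
                 lts_input_regime = lts_input_regime,
                 has_lts = has_lts,
                 has_fs = any(grepl("FS", edges))),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("motif", x$motif_id, "| regime:", x$lts_input_regime,
      "| edges:", paste(x$edges, collapse = " "), "\n")
  invisible(x)
}

#' Enumerate the 20 circuit motifs
#'
#' Builds motifs I (two-cell RS-FS) and II (two-cell RS-LTS) plus the 18
#' three-cell motifs formed by crossing the LTS input regime (external only /
#' local only / both) with the LTS inhibition target ({FS}, {RS}, {RS, FS})
#' and the presence of the FS->LTS connection. Numbering runs column-major
#' through the regime rows in column order ({FS}, no FS->LTS), ({FS}, with),
#' ({RS}, with), ({RS, FS}, with), ({RS, FS}, no), ({RS}, no), so that IV/V
#' and VII/VIII are the LTS->FS disinhibition motifs without/with external
#' drive and IX and XII are the external-only motifs with FS->LTS. The
#' numeral-to-topology map is plain data: edit the returned list (or the
#' table from [motif_table()]) to re-map numerals without code changes.
#'
#' @return named list of 20 [motif_spec()] objects (names "I".."XX").
#' @export
enumerate_motifs <- function() {
  motifs <- list(
    I = motif_spec("I", RS_FS_EDGES, "none"),
    II = motif_spec("II", c("RS->RS", "RS->LTS", "LTS->RS"), "both"))
  columns <- list(
    list(target = "FS", fs_to_lts = FALSE),
    list(target = "FS", fs_to_lts = TRUE),
    list(target = "RS", fs_to_lts = TRUE),
    list(target = c("RS", "FS"), fs_to_lts = TRUE),
    list(target = c("RS", "FS"), fs_to_lts = FALSE),
    list(target = "RS", fs_to_lts = FALSE))
  regimes <- c("external_only", "local_only", "both")
  id <- 3L
  for (col in columns) {
    for (reg in regimes) {
      edges <- RS_FS_EDGES
      if (reg %in% c("local_only", "both")) edges <- c(edges, "RS->LTS")
      if (col$fs_to_lts) edges <- c(edges, "FS->LTS")
      edges <- c(edges, paste0("LTS->", col$target))
      numeral <- as.character(utils::as.roman(id))
      motifs[[numeral]] <- motif_spec(numeral, edges, reg)
      id <- id + 1L
    }
  }
  motifs
}

#' Motif library as a data frame
#'
#' One row per motif with its numeral, regime and edge list; convenient for
#' serialization ([motifs_to_json()]) and for editing the numeral map.
#'
#' @param motifs list of motifs, by default [enumerate_motifs()].
#' @return data.frame with columns `motif_id`, `lts_input_regime`, `edges`
#'   (a list column), `has_lts`, `has_fs`.
#' @export
motif_table <- function(motifs = enumerate_motifs()) {
  data.frame(motif_id = vapply(motifs, `[[`, "", "motif_id"),
             lts_input_regime = vapply(motifs, `[[`, "", "lts_input_regime"),
             edges = I(lapply(motifs, `[[`, "edges")),
             has_lts = vapply(motifs, `[[`, TRUE, "has_lts"),
             has_fs = vapply(motifs, `[[`, TRUE, "has_fs"),
             row.names = NULL)
}

#' Serialize the motif library to JSON
#' @param motifs list of motifs, by default [enumerate_motifs()].
#' @param path optional file to write to.
#' @return JSON string (invisibly when written to a file).
#' @export
motifs_to_json <- function(motifs = enumerate_motifs(), path = NULL) {
  x <- lapply(motifs, function(m)
    list(motif_id = m$motif_id, edges = m$edges,
         lts_input_regime = m$lts_input_regime))
  js <- jsonlite::toJSON(unname(x), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Look up a motif by numeral
#' @param motif_id roman numeral, e.g. `"VIII"`.
#' @return a [motif_spec()].
#' @export
get_motif <- function(motif_id) {
  motifs <- enumerate_motifs()
  if (!motif_id %in% names(motifs))
    stop_config("unknown motif '%s'", motif_id)
  motifs[[motif_id]]
}

#' Population sizes for a motif
#'
#' Three-cell motifs use 800 RS + 100 FS + 100 LTS; two-cell motifs use
#' 800 RS plus 200 of the single interneuron type present.
#'
#' @param motif a [motif_spec()].
#' @return named list of [cell_type_spec()] for the populated types.
#' @export
motif_cell_types <- function(motif) {
  if (motif$has_fs && motif$has_lts)
    default_cell_types(800, 100, 100)
  else if (motif$has_fs)
    default_cell_types(800, 200, 0)[c("RS", "FS")]
  else
    default_cell_types(800, 0, 200)[c("RS", "LTS")]
}

#' Assemble the random connectivity of a motif
#'
#' Samples, in a fixed canonical edge order, one Bernoulli adjacency block
#' per edge present in the motif (probabilities from [connection_probs()])
#' and one normal weight per realized synapse. Absent edges yield empty
#' blocks. Uses R's RNG, so the same seed reproduces the same network.
#'
#' @param motif a [motif_spec()].
#' @param cell_types named list of [cell_type_spec()] (defaults to
#'   [motif_cell_types()]).
#' @param clip_sign passed to [sample_weights()].
#' @return object of class `connection_matrix`: per-edge synapse lists with
#'   global neuron indices (populations concatenated in RS, FS, LTS order),
#'   plus population bookkeeping. Synaptic delay is a global 1 ms.
#' @export
assemble_network <- function(motif, cell_types = motif_cell_types(motif),
                             clip_sign = FALSE) {
  stopifnot(inherits(motif, "motif_spec"))
  counts <- vapply(cell_types, `[[`, 0L, "count")
  offsets <- cumsum(c(0L, counts))[seq_along(counts)]
  names(offsets) <- names(counts)
  blocks <- list()
  for (edge in ALL_EDGES) {
    if (!edge %in% motif$edges) next
    parts <- strsplit(edge, "->", fixed = TRUE)[[1]]
    pre <- parts[1]; post <- parts[2]
    if (!pre %in% names(counts) || !post %in% names(counts))
      stop_config("motif edge %s references an absent population", edge)
    adj <- build_connection_block(counts[[pre]], counts[[post]],
                                  edge_prob(edge),
                                  same_population = pre == post)
    idx <- which(adj, arr.ind = TRUE)
    w <- sample_weights(cell_types[[pre]], nrow(idx), clip_sign = clip_sign)
    blocks[[edge]] <- list(pre = offsets[[pre]] + idx[, 1],
                           post = offsets[[post]] + idx[, 2],
                           w = w)
  }
  structure(list(motif_id = motif$motif_id, blocks = blocks,
                 counts = counts, offsets = offsets,
                 delay_ms = 1),
            class = "connection_matrix")
}

#' Remove type-pair connections from an assembled network
#'
#' Empties the named blocks in place, leaving every other block untouched
#' (the ablation used in the PING/ING connection-knockout experiments).
#'
#' @param conn a `connection_matrix` from [assemble_network()].
#' @param edges character vector of edges to remove, e.g. `"FS->FS"`.
#' @return the modified `connection_matrix`.
#' @export
ablate_edges <- function(conn, edges) {
  stopifnot(inherits(conn, "connection_matrix"))
  for (edge in edges) {
    if (!edge %in% ALL_EDGES)
      stop_config("unknown edge '%s'", edge)
    conn$blocks[[edge]] <- NULL
  }
  conn
}

# flatten the block lists into CSR-style arrays for the compiled core
conn_to_csr <- function(conn) {
  n <- sum(conn$counts)
  pre <- unlist(lapply(conn$blocks, `[[`, "pre"), use.names = FALSE)
  post <- unlist(lapply(conn$blocks, `[[`, "post"), use.names = FALSE)
  w <- unlist(lapply(conn$blocks, `[[`, "w"), use.names = FALSE)
  if (is.null(pre)) pre <- integer(0)
  if (is.null(post)) post <- integer(0)
  if (is.null(w)) w <- numeric(0)
  ord <- order(pre)
  pre <- pre[ord]; post <- post[ord]; w <- w[ord]
  ptr <- c(0L, cumsum(tabulate(pre, nbins = n)))
  list(ptr = as.integer(ptr), post = as.integer(post - 1L), w = w)
}
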