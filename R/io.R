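# JSON I/O and built-in fixtures.

#' Write a machine network to JSON
#'
#' Schema:
#' `{"name": str, "states": [str], "edges": [{"id","tail","head","k_fwd","k_bwd"}]}`
#' with `k_bwd = 0` encoding a non-invertible edge. Rates are written at full
#' precision so a write/read round trip is bit-exact for finite doubles.
#'
#' @param net a `machine_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "machine_network"))
  obj <- list(name = net$name,
              states = net$states,
              edges = net$edges[c("id", "tail", "head", "k_fwd", "k_bwd")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a machine network from JSON
#'
#' Strict reader for the schema of [write_network()]: unknown fields are
#' refused with a message naming them, and the result is validated through
#' [build_network()].
#'
#' @param path JSON file path.
#' @return a `machine_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("name", "states", "edges")
  miss <- setdiff(req, names(obj))
  if (length(miss)) stop("network JSON is missing key(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(obj), req)
  if (length(extra)) stop("network JSON has unknown key(s): ",
                          paste(extra, collapse = ", "))
  edges <- as.data.frame(obj$edges)
  ereq <- c("id", "tail", "head", "k_fwd", "k_bwd")
  emiss <- setdiff(ereq, names(edges))
  if (length(emiss)) stop("edge entries missing key(s): ",
                          paste(emiss, collapse = ", "))
  eextra <- setdiff(names(edges), ereq)
  if (length(eextra)) stop("edge entries have unknown key(s): ",
                           paste(eextra, collapse = ", "))
  edges$k_fwd <- as.numeric(edges$k_fwd)
  edges$k_bwd <- as.numeric(edges$k_bwd)
  build_network(states = unlist(obj$states), edges = edges, name = obj$name)
}

#' Write Arrhenius parameters to JSON
#'
#' Schema: `{"prefactor": float, "node_energy": {state: float},
#' "barrier": {edge: float}, "affinity_split": {edge: float},
#' "catalytic": {edge: float}}`.
#'
#' @param params an `arrhenius_params`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_arrhenius <- function(params, path) {
  stopifnot(inherits(params, "arrhenius_params"))
  jsonlite::write_json(
    list(prefactor = params$prefactor,
         node_energy = as.list(params$node_energy),
         barrier = as.list(params$barrier),
         affinity_split = as.list(params$affinity_split),
         catalytic = as.list(params$catalytic)),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read Arrhenius parameters from JSON
#' @param path JSON file path.
#' @return an `arrhenius_params`.
#' @export
read_arrhenius <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arrhenius_params(prefactor = obj$prefactor,
                   node_energy = unlist(obj$node_energy),
                   barrier = unlist(obj$barrier),
                   affinity_split = unlist(obj$affinity_split),
                   catalytic = if (length(obj$catalytic))
                     unlist(obj$catalytic) else numeric(0))
}

#' Built-in model fixtures
#'
#' Loads one of the package's application systems by name:
#' * `"f1"` — the two-state rotary motor ([f1_model()]);
#' * `"kp-classic"` — the classic two-ladder proofreader
#'   ([classic_kp_model()], returns its list of two networks);
#' * `"kp-4cycle"` — the synthetic four-cycle proofreading network
#'   ([kp_fixture()]);
#' * `"mm-competitive"`, `"mm-uncompetitive"` — dead-end inhibition networks;
#' * `"mm-noncompetitive"` — the leaky-loop inhibition network with the
#'   futile-loop projection applied.
#'
#' @param name fixture name.
#' @return a `machine_network` (or, for `"kp-classic"`, a list of two plus the
#'   error rate).
#' @export
load_fixture <- function(name) {
  switch(name,
         "f1" = f1_model(),
         "kp-classic" = classic_kp_model(delta = 3),
         "kp-4cycle" = kp_fixture(),
         "mm-competitive" = mm_inhibition_network("competitive"),
         "mm-uncompetitive" = mm_inhibition_network("uncompetitive"),
         "mm-noncompetitive" = mm_inhibition_network("noncompetitive",
                                                     project_fleak = TRUE),
         stop("unknown fixture: ", name, " (available: f1, kp-classic, ",
              "kp-4cycle, mm-competitive, mm-uncompetitive, ",
              "mm-noncompetitive)"))
}
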