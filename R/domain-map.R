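#' Construct a domain map
#'
#' A domain map names selections of bead indices over a topology: the rigid
#' core (`Fc`), the antigen-binding arms (`Fab_k`), their binding loops
#' (`CDR_k`), and any accessory selections (J-chain, glycans).  The map
#' records which domains are Fab arms and which CDR selection belongs to
#' each Fab.
#'
#' @param domains Named list of integer bead-index vectors.
#' @param fab_ids Character vector: names of the Fab domains, in order.
#' @param cdr_of Named character vector mapping each Fab name to its CDR
#'   selection name.
#' @param topology Optional [bead_structure()] used to validate indices.
#'
#' @return A `domain_map` object.
#' @export
domain_map <- function(domains, fab_ids = character(), cdr_of = character(),
                       topology = NULL) {
  if (is.null(names(domains)) || any(!nzchar(names(domains)))) {
    stop("all domains must be named", call. = FALSE)
  }
  if (anyDuplicated(names(domains))) {
    stop("duplicate domain name: ",
         names(domains)[duplicated(names(domains))][1], call. = FALSE)
  }
  domains <- lapply(domains, function(ix) sort(unique(as.integer(ix))))
  if (!is.null(topology)) {
    nb <- nrow(topology)
    for (nm in names(domains)) {
      ix <- domains[[nm]]
      if (length(ix) == 0 || any(ix < 1 | ix > nb)) {
        stop("domain '", nm, "' has indices outside the topology (1..", nb,
             ")", call. = FALSE)
      }
    }
  }
  miss <- setdiff(fab_ids, names(domains))
  if (length(miss) > 0) {
    stop("fab_ids not present among domains: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (fab in names(cdr_of)) {
    cdr <- cdr_of[[fab]]
    if (!fab %in% names(domains) || !cdr %in% names(domains)) {
      stop("cdr_of refers to unknown domain: ", fab, " -> ", cdr,
           call. = FALSE)
    }
    if (!all(domains[[cdr]] %in% domains[[fab]])) {
      stop("CDR selection '", cdr, "' is not a subset of its Fab '", fab, "'",
           call. = FALSE)
    }
  }
  structure(
    list(domains = domains, fab_ids = as.character(fab_ids),
         cdr_of = cdr_of),
    class = "domain_map"
  )
}

#' @export
print.domain_map <- function(x, ...) {
  cat("# Domain map:", length(x$domains), "domains,",
      length(x$fab_ids), "Fab arm(s)\n")
  sizes <- vapply(x$domains, length, integer(1))
  cat(paste0("  ", names(sizes), " (", sizes, " beads)", collapse = "\n"),
      "\n")
  invisible(x)
}

#' Tidy a domain map into a long tibble
#'
#' @param x A [domain_map()].
#' @param ... Unused.
#' @return A tibble with columns `domain`, `bead_id`.
#' @method tidy domain_map
#' @export
tidy.domain_map <- function(x, ...) {
  tibble::tibble(
    domain = rep(names(x$domains), vapply(x$domains, length, integer(1))),
    bead_id = unlist(x$domains, use.names = FALSE)
  )
}

#' Load a domain map from a YAML configuration
#'
#' The configuration names each domain either by explicit bead indices
#' (`beads: [1, 2, 3]`) or by chain/residue ranges
#' (`chains: [A, B]`, `residues: [340, 576]` meaning an inclusive range),
#' and may list `fab_ids` and a `cdr_of` mapping.  Selections are resolved
#' against the topology into explicit bead indices.
#'
#' @param path Path to a YAML file with a top-level `domains` mapping and
#'   optional `fab_ids`, `cdr_of` entries.
#' @param topology The [bead_structure()] the selections refer to.
#'
#' @return A validated [domain_map()].
#' @export
load_domain_map <- function(path, topology) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$domains)) stop("config has no 'domains' entry",
                                 call. = FALSE)
  if (anyDuplicated(names(cfg$domains))) {
    stop("duplicate domain name in config", call. = FALSE)
  }
  domains <- lapply(names(cfg$domains), function(nm) {
    resolve_selection(cfg$domains[[nm]], topology, nm)
  })
  names(domains) <- names(cfg$domains)
  cdr_of <- character()
  if (!is.null(cfg$cdr_of)) cdr_of <- unlist(cfg$cdr_of)
  domain_map(domains, fab_ids = as.character(cfg$fab_ids %||% character()),
             cdr_of = cdr_of, topology = topology)
}

resolve_selection <- function(sel, topology, nm) {
  if (!is.null(sel$beads)) {
    ix <- as.integer(unlist(sel$beads))
  } else {
    keep <- rep(TRUE, nrow(topology))
    if (!is.null(sel$chains)) {
      keep <- keep & topology$chain_id %in% as.character(unlist(sel$chains))
    }
    if (!is.null(sel$residues)) {
      rng <- as.integer(unlist(sel$residues))
      if (length(rng) != 2) {
        stop("domain '", nm, "': 'residues' must be a [first, last] pair",
             call. = FALSE)
      }
      keep <- keep & topology$residue_index >= rng[1] &
        topology$residue_index <= rng[2]
    }
    ix <- which(keep)
  }
  if (length(ix) == 0) {
    stop("domain '", nm, "' resolves to no beads in the topology",
         call. = FALSE)
  }
  ix
}

#' Write a domain map to a YAML configuration
#'
#' Emits explicit bead indices so the file round-trips exactly through
#' [load_domain_map()].
#'
#' @param map A [domain_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domain_map <- function(map, path) {
  cfg <- list(
    domains = lapply(map$domains, function(ix) list(beads = as.integer(ix))),
    fab_ids = as.list(map$fab_ids),
    cdr_of = as.list(map$cdr_of)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
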