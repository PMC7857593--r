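#' Particle topology tables
#'
#' A topology assigns every particle of a membrane system to a group and,
#' where relevant, to a molecule and a residue.  Groups follow the roles the
#' downstream analyses use: `"TAG"` for neutral-lipid particles, `"RESIDUE"`
#' for protein residue particles, `"HEADGROUP"` for phospholipid head-group
#' markers, `"SITE"` for binding-trap sites, and `"OTHER"` for everything
#' else.
#'
#' @param particle_id integer vector of 0-based particle indices; must be
#'   unique and contiguous starting at 0.
#' @param name character vector of short particle names.
#' @param group character vector; each element one of
#'   `"TAG"`, `"RESIDUE"`, `"HEADGROUP"`, `"SITE"`, `"OTHER"`.
#' @param molecule_id integer vector: which TAG molecule (or residue
#'   instance) a particle belongs to.  Required for every `"TAG"` particle.
#' @param residue_number integer vector or `NA`: the residue number (e.g.
#'   166 for S166).  Required for every `"RESIDUE"` particle.
#' @param leaflet character vector; `"UPPER"`, `"LOWER"` or `"UNASSIGNED"`.
#'
#' @return A `data.frame` of class `tag_topology` with one row per particle.
#' @export
#' @examples
#' top <- topology(
#'   particle_id = 0:2, name = c("TAG", "TAG", "S166"),
#'   group = c("TAG", "TAG", "RESIDUE"),
#'   molecule_id = c(0L, 1L, 0L), residue_number = c(NA, NA, 166L)
#' )
topology <- function(particle_id, name, group,
                     molecule_id = NA_integer_,
                     residue_number = NA_integer_,
                     leaflet = "UNASSIGNED") {
  n <- length(particle_id)
  top <- data.frame(
    particle_id = as.integer(particle_id),
    name = as.character(name),
    group = as.character(group),
    molecule_id = as.integer(rep_len(molecule_id, n)),
    residue_number = as.integer(rep_len(residue_number, n)),
    leaflet = as.character(rep_len(leaflet, n)),
    stringsAsFactors = FALSE
  )
  class(top) <- c("tag_topology", "data.frame")
  validate_topology(top)
  top
}

TOPOLOGY_GROUPS <- c("TAG", "RESIDUE", "HEADGROUP", "SITE", "OTHER")
LEAFLET_LEVELS <- c("UPPER", "LOWER", "UNASSIGNED")

#' Validate a topology table
#'
#' Checks the structural invariants: particle ids unique and contiguous from
#' 0, known group and leaflet labels, every TAG particle carrying a
#' `molecule_id` and every RESIDUE particle a `residue_number`.
#'
#' @param top a [topology()] table.
#' @return `top`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_topology <- function(top) {
  req <- c("particle_id", "name", "group", "molecule_id",
           "residue_number", "leaflet")
  missing_cols <- setdiff(req, names(top))
  if (length(missing_cols) > 0L) {
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ids <- top$particle_id
  if (anyDuplicated(ids) || !identical(sort(ids), seq_len(nrow(top)) - 1L)) {
    stop("topology particle_ids must be unique and contiguous from 0")
  }
  bad_group <- setdiff(unique(top$group), TOPOLOGY_GROUPS)
  if (length(bad_group) > 0L) {
    stop("unknown topology group(s): ", paste(bad_group, collapse = ", "))
  }
  bad_leaflet <- setdiff(unique(top$leaflet), LEAFLET_LEVELS)
  if (length(bad_leaflet) > 0L) {
    stop("unknown leaflet label(s): ", paste(bad_leaflet, collapse = ", "))
  }
  tag <- top$group == "TAG"
  if (any(tag & is.na(top$molecule_id))) {
    stop("every TAG particle needs a molecule_id")
  }
  res <- top$group == "RESIDUE"
  if (any(res & is.na(top$residue_number))) {
    stop("every RESIDUE particle needs a residue_number")
  }
  invisible(top)
}

#' Read / write a topology sidecar CSV
#'
#' The sidecar dialect is a plain CSV with header
#' `particle_id,name,group,molecule_id,residue_number,leaflet`.
#'
#' @param path file path.
#' @return `read_topology()` returns a validated [topology()];
#'   `write_topology()` returns `path` invisibly.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  topology(
    particle_id = df$particle_id, name = df$name, group = df$group,
    molecule_id = df$molecule_id, residue_number = df$residue_number,
    leaflet = if (is.null(df$leaflet)) "UNASSIGNED" else df$leaflet
  )
}

#' @rdname read_topology
#' @param top a [topology()] table.
#' @export
write_topology <- function(top, path) {
  validate_topology(top)
  utils::write.csv(as.data.frame(top), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# particle ids (0-based) for a group, optionally filtered
topology_group_ids <- function(top, group) {
  top$particle_id[top$group == group]
}

# 0-based ids of all particles of one residue_number
residue_particle_ids <- function(top, residue_number) {
  ids <- top$particle_id[top$group == "RESIDUE" &
                           !is.na(top$residue_number) &
                           top$residue_number == residue_number]
  if (length(ids) == 0L) {
    stop("residue ", residue_number, " not present in topology")
  }
  ids
}

# 0-based ids of particles of one TAG molecule
tag_molecule_particle_ids <- function(top, molecule_id) {
  ids <- top$particle_id[top$group == "TAG" & top$molecule_id == molecule_id]
  if (length(ids) == 0L) {
    stop("TAG molecule ", molecule_id, " not present in topology")
  }
  ids
}
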