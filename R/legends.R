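#' Code tables (legends) and the legend registry
#'
#' Every categorical layer refers to a registered legend by `legend_id`.
#' A legend is a table of unique integer codes and human-readable labels.
#' The package ships editable default legends for the synthetic land-cover,
#' Koeppen-Geiger climate, wetland, field-size, forest-management, biome and
#' livestock-region code tables (see
#' `system.file("extdata/legends.yaml", package = "habitatmapr")`), plus the
#' two-level IUCN habitat legend built by [habitat_legend()].
#'
#' @param name legend identifier.
#' @param codes integer vector of unique codes.
#' @param labels character vector of non-empty labels, same length.
#' @return An object of class `hm_legend` with fields `name`, `codes`,
#'   `labels`.
#' @export
hm_legend <- function(name, codes, labels) {
  codes <- as.integer(codes)
  labels <- as.character(labels)
  stopifnot(length(codes) == length(labels), !anyDuplicated(codes),
            !any(is.na(codes)), all(nzchar(labels)))
  structure(list(name = name, codes = codes, labels = labels),
            class = "hm_legend")
}

#' @export
print.hm_legend <- function(x, ...) {
  cat(sprintf("<legend '%s'> %d codes\n", x$name, length(x$codes)))
  invisible(x)
}

.legend_registry <- new.env(parent = emptyenv())

#' @rdname hm_legend
#' @param legend an `hm_legend` to register (replaces any legend of the same
#'   name).
#' @export
register_legend <- function(legend) {
  stopifnot(inherits(legend, "hm_legend"))
  assign(legend$name, legend, envir = .legend_registry)
  invisible(legend)
}

#' @rdname hm_legend
#' @export
get_legend <- function(name) {
  if (!exists(name, envir = .legend_registry, inherits = FALSE))
    stop("no legend registered under '", name, "'")
  get(name, envir = .legend_registry, inherits = FALSE)
}

#' @rdname hm_legend
#' @export
legend_names <- function() sort(ls(envir = .legend_registry))

#' Read legends from a YAML file and register them
#'
#' The file maps legend name to a `{code: label}` table. Shipping legends as
#' data means real product code tables (e.g. a Copernicus legend) can be
#' swapped in without code changes.
#'
#' @param path YAML file path.
#' @return Named list of the registered legends, invisibly.
#' @export
load_legends <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(names(doc), function(nm) {
    entries <- doc[[nm]]
    register_legend(hm_legend(nm, as.integer(names(entries)),
                              unlist(entries, use.names = FALSE)))
  })
  names(out) <- names(doc)
  invisible(out)
}

# ---- IUCN habitat legend -----------------------------------------------

#' The two-level IUCN habitat legend
#'
#' Level-2 habitat classes are encoded as scalar integers
#' `level1 * 100 + minor` (class 1.6 -> 106, 14.5 -> 1405); minor 0 marks the
#' Level-1 default class used when no Level-2 rule matches. The legend covers
#' the terrestrial classes the default ruleset can emit; marine and other
#' unmappable Level-1 groups (9-13, 15, 16) are registered but flagged
#' `mappable = FALSE`.
#'
#' @return A data frame with columns `code`, `level1`, `minor`, `label`,
#'   `mappable`.
#' @examples
#' h <- habitat_legend()
#' h[h$code == 106, ]
#' @export
habitat_legend <- function() {
  e <- function(code, label, mappable = TRUE) {
    code <- as.integer(code)
    data.frame(code = code, level1 = code %/% 100L, minor = code %% 100L,
               label = label, mappable = mappable)
  }
  rbind(
    e(100,  "Forest (Level 1 default)"),
    e(101,  "Forest - Boreal"),
    e(104,  "Forest - Temperate"),
    e(105,  "Forest - Subtropical/tropical dry"),
    e(106,  "Forest - Subtropical/tropical moist lowland"),
    e(107,  "Forest - Subtropical/tropical mangrove vegetation"),
    e(108,  "Forest - Subtropical/tropical swamp"),
    e(109,  "Forest - Subtropical/tropical moist montane"),
    e(200,  "Savanna (Level 1 default)"),
    e(201,  "Savanna - Dry"),
    e(202,  "Savanna - Moist"),
    e(300,  "Shrubland (Level 1 default)"),
    e(304,  "Shrubland - Temperate"),
    e(305,  "Shrubland - Subtropical/tropical dry"),
    e(308,  "Shrubland - Mediterranean-type"),
    e(400,  "Grassland (Level 1 default)"),
    e(404,  "Grassland - Temperate"),
    e(405,  "Grassland - Subtropical/tropical dry lowland"),
    e(407,  "Grassland - Subtropical/tropical high altitude"),
    e(500,  "Wetlands inland (Level 1 default)"),
    e(503,  "Wetlands - Shrub dominated"),
    e(504,  "Wetlands - Bogs, marshes, swamps, fens, peatlands"),
    e(505,  "Wetlands - Permanent freshwater lakes"),
    e(600,  "Rocky Areas"),
    e(800,  "Desert (Level 1 default)"),
    e(801,  "Desert - Hot"),
    e(802,  "Desert - Temperate"),
    e(803,  "Desert - Cold"),
    e(900,  "Marine Neritic", FALSE),
    e(1000, "Marine Oceanic", FALSE),
    e(1100, "Marine Deep Ocean Floor", FALSE),
    e(1200, "Marine Intertidal", FALSE),
    e(1300, "Marine Coastal/Supratidal", FALSE),
    e(1400, "Artificial Terrestrial (Level 1 default)"),
    e(1401, "Arable Land"),
    e(1402, "Pastureland"),
    e(1403, "Plantations"),
    e(1404, "Rural Gardens"),
    e(1405, "Urban Areas"),
    e(1500, "Artificial Aquatic", FALSE),
    e(1600, "Introduced Vegetation", FALSE)
  )
}

register_habitat_legend <- function() {
  h <- habitat_legend()
  register_legend(hm_legend("iucn_habitat", h$code, h$label))
}

#' Project Level-2 habitat codes to Level 1
#'
#' Integer division of the decade encoding by 100; `NA` passes through.
#' Unregistered codes are an error — every code the pipeline emits must be in
#' the habitat legend.
#'
#' @param code integer vector of habitat codes (`NA` allowed).
#' @return Integer vector of Level-1 codes.
#' @examples
#' level1_of(c(106, 1405, NA))  # 1, 14, NA
#' @export
level1_of <- function(code) {
  known <- habitat_legend()$code
  bad <- !is.na(code) & !(code %in% known)
  if (any(bad))
    stop("unregistered habitat code(s): ",
         paste(unique(code[bad]), collapse = ", "))
  as.integer(code %/% 100L)
}

# ---- Koeppen-Geiger groups ---------------------------------------------

#' Major Koeppen-Geiger group of a climate zone code
#'
#' Maps fine climate-zone codes (e.g. Af, BWh, Cfa, Dfc, ET) to the five
#' major groups by the first letter of their legend label: A Tropical,
#' B Arid, C Temperate, D Continental, E Polar. The climatic suitability for
#' forest cover used by the pastureland definition is membership of
#' {Tropical, Temperate, Continental}.
#'
#' @param zone_code integer vector of zone codes (`NA` allowed).
#' @param legend the Koeppen legend (default: registered `"koppen"`).
#' @return Character vector of group names (`NA` preserved).
#' @export
koppen_group <- function(zone_code, legend = get_legend("koppen")) {
  idx <- match(zone_code, legend$codes)
  bad <- !is.na(zone_code) & is.na(idx)
  if (any(bad))
    stop("unknown Koeppen zone code(s): ",
         paste(unique(zone_code[bad]), collapse = ", "))
  groups <- c(A = "Tropical", B = "Arid", C = "Temperate",
              D = "Continental", E = "Polar")
  first <- toupper(substr(legend$labels[idx], 1, 1))
  unknown <- !is.na(first) & !(first %in% names(groups))
  if (any(unknown))
    stop("Koeppen label(s) not starting with A-E: ",
         paste(unique(legend$labels[idx][unknown]), collapse = ", "))
  unname(groups[first])
}

#' @rdname koppen_group
#' @param group character vector of major group names.
#' @param forest_groups groups considered climatically forest-suitable.
#' @return `forest_suitable_climate()`: logical vector (`NA` -> `FALSE`).
#' @export
forest_suitable_climate <- function(group,
                                    forest_groups = c("Tropical", "Temperate",
                                                      "Continental")) {
  !is.na(group) & group %in% forest_groups
}

# Register package defaults when the namespace loads.
.onLoad <- function(libname, pkgname) {
  register_habitat_legend()
  path <- system.file("extdata", "legends.yaml", package = pkgname)
  if (nzchar(path)) load_legends(path)
  invisible()
}
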