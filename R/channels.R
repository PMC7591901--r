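#' Density channel schemes
#'
#' A channel scheme maps each protein heavy atom to one or more density
#' channels. The `"default"` scheme has 11 channels: four element channels
#' (C, N, O, S), six physico-chemical property channels assigned from a
#' residue/atom-name lookup for the 20 standard amino acids (hydrophobic,
#' aromatic, hydrogen-bond donor, hydrogen-bond acceptor, formally positive,
#' formally negative), and one total heavy-atom occupancy channel. The
#' `"minimal"` scheme (C, N, O, occupancy) is a light profile for
#' desk-scale experiments. Atoms whose element is not recognized fall back
#' to the occupancy channel alone, with a warning.
#'
#' @param name Scheme name.
#' @return A list with `name`, `n_channels`, `channel_names`, and an
#'   `assign` function taking an atom tibble and returning a list of
#'   integer channel-index vectors.
#' @export
get_channel_scheme <- function(name = "default") {
  switch(name,
    default = .scheme_default(),
    minimal = .scheme_minimal(),
    rlang::abort(paste0("unknown channel scheme: ", name))
  )
}

#' @rdname get_channel_scheme
#' @export
channel_scheme_size <- function(name = "default") {
  get_channel_scheme(name)$n_channels
}

# side-chain atom names carrying each property, per standard residue
.AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

.DONOR_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG"
)

.ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

.POSITIVE_ATOMS <- list(ARG = c("NE", "NH1", "NH2", "CZ"), LYS = "NZ")
.NEGATIVE_ATOMS <- list(ASP = c("CG", "OD1", "OD2"),
                        GLU = c("CD", "OE1", "OE2"))

.HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET",
                      "TRP", "GLY", "CYS")

.match_table <- function(resname, name, table) {
  idx <- match(resname, names(table))
  out <- logical(length(resname))
  hit <- !is.na(idx)
  if (any(hit)) {
    out[hit] <- mapply(function(i, nm) nm %in% table[[i]],
                       idx[hit], name[hit])
  }
  out
}

.scheme_default <- function() {
  channel_names <- c("C", "N", "O", "S", "hydrophobic", "aromatic",
                     "donor", "acceptor", "positive", "negative",
                     "occupancy")
  assign <- function(atoms) {
    n <- nrow(atoms)
    el <- atoms$element
    known <- el %in% c("C", "N", "O", "S")
    if (any(!known)) {
      rlang::warn(paste0("unrecognized element(s) mapped to occupancy ",
                         "channel only: ",
                         paste(unique(el[!known]), collapse = ", ")))
    }
    elem_ch <- match(el, c("C", "N", "O", "S"))
    hydrophobic <- el == "C" & atoms$resname %in% .HYDROPHOBIC_RES
    aromatic <- .match_table(atoms$resname, atoms$name, .AROMATIC_ATOMS)
    donor <- (atoms$name == "N" & el == "N") |
      .match_table(atoms$resname, atoms$name, .DONOR_ATOMS)
    acceptor <- (atoms$name %in% c("O", "OXT") & el == "O") |
      .match_table(atoms$resname, atoms$name, .ACCEPTOR_ATOMS)
    positive <- .match_table(atoms$resname, atoms$name, .POSITIVE_ATOMS)
    negative <- .match_table(atoms$resname, atoms$name, .NEGATIVE_ATOMS)
    lapply(seq_len(n), function(i) {
      ch <- integer(0)
      if (known[i]) ch <- elem_ch[i]
      if (known[i]) {
        props <- which(c(hydrophobic[i], aromatic[i], donor[i],
                         acceptor[i], positive[i], negative[i]))
        ch <- c(ch, 4L + props)
      }
      c(ch, 11L)
    })
  }
  list(name = "default", n_channels = 11L,
       channel_names = channel_names, assign = assign)
}

.scheme_minimal <- function() {
  channel_names <- c("C", "N", "O", "occupancy")
  assign <- function(atoms) {
    el <- atoms$element
    known <- el %in% c("C", "N", "O")
    elem_ch <- match(el, c("C", "N", "O"))
    lapply(seq_len(nrow(atoms)), function(i) {
      if (known[i]) c(elem_ch[i], 4L) else 4L
    })
  }
  list(name = "minimal", n_channels = 4L,
       channel_names = channel_names, assign = assign)
}
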