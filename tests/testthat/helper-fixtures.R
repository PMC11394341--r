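# shared fixture builders and independent oracles

mini_grid <- function(nr = 10, nc = 10, size = 0.05, lon = 103, lat = 31) {
  grid_spec(nr, nc, size, origin_lon = lon, origin_lat = lat)
}

stack_of <- function(grid, ...) {
  env_stack(grid, list(...))
}

# independent connected-component oracle: queue-based BFS, one cell at a time
bfs_label_oracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab_next <- 0L
  offs <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    lab_next <- lab_next + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- lab_next
    while (length(queue) > 0) {
      rc <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        rr <- rc[1] + offs[k, 1]; cc <- rc[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- lab_next
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# partition signature invariant to label numbering
component_signature <- function(lab) {
  groups <- split(seq_along(lab), as.vector(lab))
  groups <- groups[names(groups) != "0"]
  unname(groups[order(vapply(groups, min, numeric(1)))])
}

# haversine great-circle distance on the 6371-km sphere, written out in full
# as an oracle independent of geosphere
haversine_oracle <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * 6371 * asin(sqrt(pmin(1, sqrt(a))^2))
}

paper_area_table <- function() {
  read.csv(system.file("extdata", "habitat_area_table.csv",
                       package = "preyhab"), stringsAsFactors = FALSE)
}

paper_core_sites <- function() {
  read.csv(system.file("extdata", "core_site_table.csv",
                       package = "preyhab"), stringsAsFactors = FALSE)
}
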