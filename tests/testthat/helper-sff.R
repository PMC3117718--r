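# byte-level SFF v1 writer used to build binary fixtures at test time.
# Kept independent of the package reader: every field is assembled by
# hand from the published layout (big-endian, 8-byte padded sections).

u16be <- function(x) as.raw(c(x %/% 256, x %% 256))
u32be <- function(x) as.raw((x %/% 256^(3:0)) %% 256)
u64be <- function(x) as.raw((x %/% 256^(7:0)) %% 256)
pad8 <- function(bytes) {
  r <- length(bytes) %% 8
  if (r == 0) bytes else c(bytes, raw(8 - r))
}

# seqs/quals are the FULL (unclipped) base calls; clips are 1-based
# inclusive as stored in the file (0 = unset)
write_sff <- function(path, ids, seqs, quals,
                      clip_qual_left = rep(0L, length(ids)),
                      clip_qual_right = rep(0L, length(ids)),
                      clip_adapter_left = rep(0L, length(ids)),
                      clip_adapter_right = rep(0L, length(ids)),
                      n_flows = 400L, key = "TCAG") {
  flow_chars <- paste(rep("TACG", n_flows / 4), collapse = "")
  header <- c(charToRaw(".sff"), u32be(1),      # magic, version
              u64be(0), u32be(0),               # index offset/length
              u32be(length(ids)),
              raw(2),                           # header_length placeholder
              u16be(nchar(key)), u16be(n_flows),
              as.raw(1),                        # flowgram format code
              charToRaw(flow_chars), charToRaw(key))
  header <- pad8(header)
  header[25:26] <- u16be(length(header))
  body <- raw(0)
  for (i in seq_along(ids)) {
    nb <- nchar(seqs[i])
    rh <- c(raw(2),                             # read_header_length placeholder
            u16be(nchar(ids[i])), u32be(nb),
            u16be(clip_qual_left[i]), u16be(clip_qual_right[i]),
            u16be(clip_adapter_left[i]), u16be(clip_adapter_right[i]),
            charToRaw(ids[i]))
    rh <- pad8(rh)
    rh[1:2] <- u16be(length(rh))
    flows <- as.raw(rep(0L, 2 * n_flows))       # flow values, unused
    flow_idx <- as.raw(rep(1L, nb))
    data <- pad8(c(flows, flow_idx, charToRaw(seqs[i]), as.raw(quals[[i]])))
    body <- c(body, rh, data)
  }
  writeBin(c(header, body), path)
  path
}
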