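# Small fixture builders used across test files.

# cp_dataset from a genes x samples matrix of Cp values (1 bio, 1 tech rep)
cp_from_matrix <- function(m, n_bio = 1L) {
  df <- expand.grid(gene = rownames(m), sample = colnames(m),
                    bio_rep = seq_len(n_bio), tech_rep = 1L,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$cp <- m[cbind(df$gene, df$sample)]
  cp_dataset(df)
}

# long-format CSV on disk from a data frame; returns the path
write_fixture_csv <- function(df, name = "fixture.csv") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

tiny_long_df <- function() {
  data.frame(gene = rep(c("g1", "g2"), each = 2),
             sample = rep(c("s1", "s2"), times = 2),
             bio_rep = 1L, tech_rep = 1L,
             cp = c(20, 21, 24.5, 23.5))
}
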