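# Independent SQL oracle: load the world's tables into sqlite3 (via the
# system python) and run a query there.  Used only for plain SELECTs
# without registered scalar functions.
sqlite_oracle <- function(db, sql) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  for (nm in names(db$tables)) {
    utils::write.csv(db$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import csv, glob, json, os, sqlite3, sys",
    "con = sqlite3.connect(':memory:')",
    "d = sys.argv[1]",
    "for path in sorted(glob.glob(os.path.join(d, '*.csv'))):",
    "    name = os.path.splitext(os.path.basename(path))[0]",
    "    with open(path) as fh:",
    "        rows = list(csv.reader(fh))",
    "    cols = rows[0]",
    "    con.execute('CREATE TABLE %s (%s)' % (name, ','.join(cols)))",
    "    con.executemany('INSERT INTO %s VALUES (%s)' % (name, ','.join(['?'] * len(cols))), rows[1:])",
    "cur = con.execute(sys.argv[2])",
    "out = sorted(set(tuple(r) for r in cur.fetchall()))",
    "print(json.dumps(out))"), script)
  res <- system2("python", c(script, dir, shQuote(sql)), stdout = TRUE)
  vals <- jsonlite::fromJSON(paste(res, collapse = ""), simplifyVector = TRUE)
  if (length(vals) == 0L) return(character())
  sort(as.character(unlist(vals)))
}
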