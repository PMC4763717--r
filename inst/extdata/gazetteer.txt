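# unambiguous US place names, lowercase, one per line; ambiguous names
# (e.g. london, paris, portland-style collisions abroad) are excluded
chicago
new york
los angeles
houston
philadelphia
phoenix
san antonio
san diego
seattle
denver
boston
dallas
miami
atlanta
detroit
baltimore
milwaukee
sacramento
minneapolis
pittsburgh
cincinnati
cleveland
nashville
indianapolis
[aliases]
united states
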