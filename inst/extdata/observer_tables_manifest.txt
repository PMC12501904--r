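md5: 572c7ee9078df0e57a6457bc35f06ecf
file: observer_tables_5nm.csv
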