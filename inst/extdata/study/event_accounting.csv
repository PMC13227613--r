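quantity,count
entries_total,1241
series_entries,100
events_from_series,216
excluded_no_time,82
excluded_no_label,62
excluded_both,17
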