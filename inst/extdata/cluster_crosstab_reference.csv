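block,group,cold_spot,hot_spot
seifa,most_advantaged,171,24
seifa,advantaged,128,61
seifa,medium,94,99
seifa,disadvantaged,71,140
seifa,most_disadvantaged,84,141
indigenous,low,384,72
indigenous,high,164,393
interaction,low_most_advantaged,159,17
interaction,low_advantaged,94,17
interaction,low_medium,61,22
interaction,low_disadvantaged,33,11
interaction,low_most_disadvantaged,37,5
interaction,high_most_advantaged,12,7
interaction,high_advantaged,34,44
interaction,high_medium,33,77
interaction,high_disadvantaged,38,129
interaction,high_most_disadvantaged,47,136
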