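Samples,Replicates,Scoring
Control,1,3A3
Control,1,5A3
Control,1,3A3
Control,2,4A3
Control,2,2A3
Control,2,2A3
GR24 10-7M,1,3A3
GR24 10-7M,1,3A3
GR24 10-7M,1,3A3
GR24 10-7M,2,5A3
GR24 10-7M,2,5A3
GR24 10-7M,3,5A3
MP3 10-8M,1,4A3
MP3 10-8M,1,5A3
MP3 10-8M,1,4A3
MP3 10-8M,2,3A2
MP3 10-8M,2,5A3
MP3 10-8M,2,5A3
MP1 10-7M,1,3A2
MP1 10-7M,1,5A2
MP1 10-7M,1,1A2
MP1 10-7M,2,3A2
MP1 10-7M,2,2A3
MP1 10-7M,2,2A3
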