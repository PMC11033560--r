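image,expert_count,instance_counted,instance_overlooked,instance_overcounted,semantic_counted,semantic_overlooked,semantic_overcounted
Amo-1-B1,2,4,0,2,3,0,1
Amo-2-C4,5,5,1,1,6,0,1
Amo-3-B5,4,5,0,1,4,0,0
Amo-4-H3,5,4,3,2,6,0,1
Amo-5-A4,9,6,3,0,9,0,0
Chr-1-D2,5,1,4,0,5,0,0
Chr-3-B5,5,3,2,0,6,0,1
Chr-4-A2,9,7,2,0,8,1,0
Chr-5-E3,3,2,2,1,4,0,1
Chr-5-E4,8,4,4,0,6,2,0
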