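allele	activity	defining_rsids	note
*1	full		reference allele; empty defining set
*2	full		
*33	full	rs28371717	
*35	full		
*39	full		
*53	full		also listed semi-functional; first listing retained
*9	semi		
*10	semi		
*17	semi		
*29	semi		
*36	semi		
*41	semi		also covered by the null range *40-*42; first listing retained
*54	semi		
*59	semi		
*72	semi		
*84	semi		
*3	null		
*4	null	rs3892097	
*5	null		
*6	null		
*7	null		
*8	null		
*11	null		
*12	null		
*14	null		
*15	null		
*16	null		
*18	null		
*19	null		
*20	null		
*21	null		
*38	null		
*40	null		
*42	null		
*44	null		
*51	null		
*56	null		
*57	null		
*60	null		
*62	null		
*68	null		
*69	null		
*92	null		
*96	null		
*99	null		
*100	null		
*101	null		
*114	null		
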