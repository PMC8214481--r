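lhs	rhs	support	confidence	coverage	lift	count	n_transactions
Chenpi	Banxia	0.258	0.701	0.368	1.939	387	1499
Banxia	Chenpi	0.258	0.714	0.362	1.939	387	1499
Chenpi	Fuling	0.294	0.799	0.368	1.337	441	1499
Baizhu	Fuling	0.261	0.795	0.328	1.330	391	1499
Chuanxiong	Danshen	0.203	0.540	0.376	1.301	304	1499
Danggui	Huangqi	0.388	0.758	0.511	1.285	581	1499
Huangqi	Danggui	0.388	0.656	0.590	1.285	581	1499
Banxia	Fuling	0.273	0.755	0.362	1.262	409	1499
Banxia	Dangshen	0.201	0.555	0.362	1.256	301	1499
Dangshen	Huangqi	0.324	0.733	0.442	1.242	486	1499
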