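language	onset
en	p l
en	p r
en	b l
en	b r
en	t r
en	t w
en	d r
en	d w
en	k l
en	k r
en	k w
en	g l
en	g r
en	f l
en	f r
en	T r
en	s p
en	s t
en	s k
en	s m
en	s n
en	s l
en	s w
en	s p l
en	s p r
en	s t r
en	s k r
en	s k w
nl	p l
nl	p r
nl	b l
nl	b r
nl	t r
nl	t w
nl	d r
nl	d w
nl	k l
nl	k r
nl	k n
nl	k w
nl	f l
nl	f r
nl	v l
nl	v r
nl	z w
nl	s p
nl	s t
nl	s k
nl	s l
nl	s m
nl	s n
nl	s x
nl	s p r
nl	s t r
nl	s x r
de	p l
de	p R
de	b l
de	b R
de	t R
de	d R
de	k l
de	k R
de	k n
de	k v
de	g l
de	g R
de	g n
de	f l
de	f R
de	S p
de	S t
de	S l
de	S m
de	S n
de	S v
de	S p R
de	S t R
de	t s v
zh	b y
zh	p y
zh	m y
zh	d y
zh	t y
zh	n y
zh	l y
zh	j y
zh	q y
zh	x y
zh	b w
zh	p w
zh	m w
zh	f w
zh	d w
zh	t w
zh	n w
zh	l w
zh	g w
zh	k w
zh	h w
zh	zh w
zh	ch w
zh	sh w
zh	r w
zh	z w
zh	c w
zh	s w
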