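# English stop words: function words removed from documents and from
# dictionary-derived item streams. One word per line; '#' starts a comment.
# Bare contraction stems (aren, ll, ve, ...) appear because tokenization
# splits on the apostrophe.
a
about
above
after
again
against
all
also
am
an
and
any
are
aren
as
at
be
because
been
before
being
below
between
both
but
by
can
cannot
could
couldn
d
did
didn
do
does
doesn
doing
don
down
during
each
either
else
etc
few
for
from
further
had
hadn
has
hasn
have
haven
having
he
her
here
hers
herself
him
himself
his
how
i
if
in
into
is
isn
it
its
itself
just
least
less
ll
m
many
may
me
might
more
most
much
must
mustn
my
myself
neither
no
nor
not
now
o
of
off
often
on
once
only
onto
or
other
our
ours
ourselves
out
over
own
per
re
s
same
shall
shan
she
should
shouldn
so
some
such
t
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
through
to
too
under
until
up
upon
ve
very
was
wasn
we
were
weren
what
when
where
which
while
who
whom
whose
why
will
with
won
would
wouldn
y
you
your
yours
yourself
yourselves
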